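#' Default noise and delay grids for resonance sweeps
#'
#' The noise grid is 25 geometrically spaced points on `[5e-4, 0.2]`
#' augmented with the physically distinguished intensities
#' `{0.001, 0.02, 0.04, 0.065, 0.08, 0.14}` (the resonant and anti-resonant
#' noise levels of the model at default parameters). The delay grid is
#' `0, 2, ..., 100`, fine enough to resolve resonances spaced by the drive
#' period 14.
#'
#' @return numeric vector of control values, sorted and unique.
#' @export
default_noise_grid <- function() {
  geo <- exp(seq(log(5e-4), log(0.2), length.out = 25))
  sort(unique(c(round(geo, 6), 0.001, 0.02, 0.04, 0.065, 0.08, 0.14)))
}

#' @rdname default_noise_grid
#' @param tau_max largest delay (default 100).
#' @param step grid step (default 2).
#' @export
default_delay_grid <- function(tau_max = 100, step = 2) {
  seq(0, tau_max, by = step)
}

# build the per-realization ISI recipe for a fixed condition
isi_recipe <- function(net, model, control, threshold = 0, refractory = 1) {
  force(net); force(model); force(control)
  function(seed) {
    ctl <- control
    ctl$seed <- as.integer(seed)
    tr <- simulate_fhn(net, model, ctl)
    extract_isis(detect_spikes(tr$X, tr$time, threshold, refractory))
  }
}

#' Run one sweep condition: simulate, extract ISIs, compute complexity
#'
#' Composes the full pipeline for a fixed parameter set: repeated network
#' simulations with incrementing seeds until `L_target` mean-field
#' inter-spike intervals are collected, then the ordinal statistical
#' complexity of the interval series. Conditions where firing never occurs
#' (or yields fewer than `d` intervals) carry the no-firing convention
#' `SCM = 0`, `NSE = 1`.
#'
#' @param net a [ws_network()].
#' @param model an [fhn_params()].
#' @param control a [sim_control()]; its `seed` seeds the first realization.
#' @param L_target intervals to collect (default 2000).
#' @param d embedding dimension (default 3).
#' @param threshold,refractory spike-detection settings.
#' @param max_realizations realization cap per condition.
#' @return list with `complexity` (a `complexity_summary`), `isi`
#'   (the `isi_series`), `n_isi`, and `misi_mean`.
#' @export
run_condition <- function(net, model, control, L_target = 2000, d = 3L,
                          threshold = 0, refractory = 1,
                          max_realizations = 100L) {
  recipe <- isi_recipe(net, model, control, threshold, refractory)
  isi <- accumulate_isis(recipe, L_target, base_seed = control$seed,
                         max_realizations = max_realizations)
  cs <- complexity_of_isi(isi, d = d)
  list(complexity = cs, isi = isi, n_isi = length(isi$intervals),
       misi_mean = if (length(isi$intervals)) mean(isi$intervals) else NA_real_)
}

#' Resonance-curve sweep over a control parameter
#'
#' Runs [run_condition()] for each value of one control parameter --
#' noise intensity `D`, delay `tau`, coupling `g`, or a network parameter
#' (`p`, `k`, `N`) -- and assembles the SCM/NSE curve with detected local
#' extrema. Conditions are seeded independently from the base seed and the
#' control value, so results do not depend on execution order and adding
#' grid points never changes existing conditions.
#'
#' @param control_name one of `"D"`, `"tau"`, `"g"`, `"p"`, `"k"`, `"N"`.
#' @param values ordered distinct control values.
#' @param net base [ws_network()] (rebuilt per value for network parameters).
#' @param model base [fhn_params()].
#' @param sim base [sim_control()].
#' @param L_target,d,threshold,refractory,max_realizations per-condition
#'   settings, see [run_condition()].
#' @param base_seed seed from which per-condition seeds are derived.
#' @param prominence prominence fraction for [find_local_extrema()].
#' @param snr logical; also estimate the spectral SNR per condition from
#'   `reps_snr` realizations of the mean field.
#' @param reps_snr realizations for the SNR average (default 30).
#' @param verbose print one progress line per condition.
#' @return An object of class `resonance_curve`: a data frame with columns
#'   `control, C, H, S, Q, n_isi, misi_mean, no_firing` (+ `snr` when
#'   requested), with the extrema and sweep metadata as attributes.
#' @export
sweep_resonance <- function(control_name, values, net, model, sim,
                            L_target = 2000, d = 3L, threshold = 0,
                            refractory = 1, max_realizations = 100L,
                            base_seed = 1L, prominence = 0.05,
                            snr = FALSE, reps_snr = 30L, verbose = FALSE) {
  control_name <- match.arg(control_name, c("D", "tau", "g", "p", "k", "N"))
  if (any(duplicated(values))) stop("control values must be distinct")
  ord <- order(values)
  rows <- vector("list", length(values))
  for (i in seq_along(values)) {
    v <- values[i]
    m <- model; s <- sim; n <- net
    if (control_name %in% c("D", "tau", "g")) {
      m[[control_name]] <- v
    } else {
      np <- list(N = net$N, k = net$k, p = net$p)
      np[[control_name]] <- v
      n <- ws_network(np$N, np$k, np$p,
                      seed = condition_seed(base_seed, v, realization = -1L))
    }
    s$seed <- condition_seed(base_seed, v)
    res <- run_condition(n, m, s, L_target = L_target, d = d,
                         threshold = threshold, refractory = refractory,
                         max_realizations = max_realizations)
    row <- data.frame(control = v, C = res$complexity$C, H = res$complexity$H,
                      S = res$complexity$S, Q = res$complexity$Q,
                      n_isi = res$n_isi, misi_mean = res$misi_mean,
                      no_firing = res$complexity$no_firing)
    if (snr) {
      reps <- lapply(seq_len(reps_snr), function(r) {
        s2 <- s; s2$seed <- condition_seed(base_seed, v, realization = r)
        simulate_fhn(n, m, s2)$X
      })
      row$snr <- estimate_snr(reps, dt = s$dt, fe = 1 / m$Te)$snr
    }
    rows[[i]] <- row
    if (verbose)
      message(sprintf("%s = %-8g C = %.4f H = %.4f n_isi = %d%s",
                      control_name, v, row$C, row$H, row$n_isi,
                      if (row$no_firing) " [no firing]" else ""))
  }
  curve <- do.call(rbind, rows)[ord, , drop = FALSE]
  rownames(curve) <- NULL
  ext <- find_local_extrema(curve$C, prominence = prominence)
  structure(curve,
            class = c("resonance_curve", "data.frame"),
            control_name = control_name,
            maxima = curve$control[ext$maxima],
            minima = curve$control[ext$minima],
            prominence = prominence,
            L_target = L_target, d = d, base_seed = base_seed)
}

#' @export
print.resonance_curve <- function(x, ...) {
  cat(sprintf("Resonance curve over %s (%d points), SCM maxima at: %s\n",
              attr(x, "control_name"), nrow(x),
              paste(format(attr(x, "maxima")), collapse = ", ")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Local extrema of a curve over an ordered control grid
#'
#' An interior point is a local maximum if strictly greater than both
#' neighbours and its prominence -- its height above the higher of the two
#' flanking valleys (the minima reached before the curve next exceeds the
#' peak on each side) -- is at least `prominence` times the curve range.
#' Minima are found symmetrically. Endpoints are never extrema; a flat
#' curve has none.
#'
#' @param y numeric curve values (>= 3 points).
#' @param prominence required prominence as a fraction of the curve range
#'   (default 0.05).
#' @return list with integer index vectors `maxima` and `minima`.
#' @export
find_local_extrema <- function(y, prominence = 0.05) {
  n <- length(y)
  if (n < 3L) stop("need at least 3 points")
  rng <- diff(range(y))
  if (rng == 0) return(list(maxima = integer(0), minima = integer(0)))
  prom_one <- function(v, i) {
    left <- v[seq_len(i - 1L)]
    hi <- which(left > v[i])
    lmin <- min(left[seq.int(if (length(hi)) max(hi) else 1L, i - 1L)])
    right <- v[(i + 1L):n]
    hi <- which(right > v[i])
    rmin <- min(right[seq_len(if (length(hi)) min(hi) else length(right))])
    v[i] - max(lmin, rmin)
  }
  scan <- function(v) {
    cand <- which(v[2:(n - 1L)] > v[1:(n - 2L)] & v[2:(n - 1L)] > v[3:n]) + 1L
    cand[vapply(cand, function(i) prom_one(v, i) >= prominence * rng, logical(1))]
  }
  list(maxima = scan(y), minima = scan(-y))
}

#' Intrinsic firing period of the noise-driven network
#'
#' With the periodic drive switched off (`A = 0`), moderate noise makes the
#' excitable network fire regularly (coherence resonance); the intrinsic
#' period `T0` is the mode of the mean-field inter-spike-interval histogram
#' (bin width 0.1 time units). `T0` sets the number of stochastic
#' resonances a drive of period `Te` can support.
#'
#' @param net a [ws_network()].
#' @param model an [fhn_params()]; `A` is forced to 0.
#' @param control a [sim_control()].
#' @param n_isi intervals to collect (default 1000).
#' @param bin histogram bin width (default 0.1).
#' @param max_realizations realization cap.
#' @return list with `T0` (bin midpoint of the modal bin), `D_used`,
#'   `n_isi`, and the `isi_series`.
#' @export
estimate_intrinsic_period <- function(net, model, control, n_isi = 1000,
                                      bin = 0.1, max_realizations = 100L) {
  model$A <- 0
  isi <- accumulate_isis(isi_recipe(net, model, control), n_isi,
                         base_seed = control$seed,
                         max_realizations = max_realizations)
  if (isi$no_firing || length(isi$intervals) < 10)
    stop("no (or too little) firing; increase D")
  iv <- isi$intervals
  breaks <- seq(0, ceiling(max(iv) / bin) * bin + bin, by = bin)
  h <- graphics::hist(iv, breaks = breaks, plot = FALSE)
  T0 <- h$mids[which.max(h$counts)]
  list(T0 = T0, D_used = model$D, n_isi = length(iv), isi = isi)
}

#' Predicted number of noise-induced resonances
#'
#' A drive period `Te` falling in the interval `(m T0, (m+1) T0)` supports
#' `m` stochastic resonances, `T0` being the intrinsic firing period. The
#' boundary `Te = m T0` resolves to `m`.
#'
#' @param Te drive period (> 0).
#' @param T0 intrinsic period (> 0).
#' @return non-negative integer `m`.
#' @examples
#' predicted_resonance_count(14, 3.45)  # 4
#' @export
predicted_resonance_count <- function(Te, T0) {
  stopifnot_scalar(Te, "Te", positive = TRUE)
  stopifnot_scalar(T0, "T0", positive = TRUE)
  as.integer(floor(Te / T0))
}

#' Export a per-neuron raster as a TSV space-time table
#'
#' Neurons in rows, recorded time points in columns, with a time header row.
#'
#' @param traj an `fhn_trajectory` simulated with `raster = TRUE`.
#' @param path output TSV file.
#' @export
export_raster <- function(traj, path) {
  if (is.null(traj$raster)) stop("trajectory has no recorded raster")
  m <- t(traj$raster)                       # neurons x time
  header <- paste(c("neuron", sprintf("%.10g", traj$raster_time)),
                  collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(sprintf("x%d", i - 1L), sprintf("%.10g", m[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname export_raster
#' @return `read_raster` returns a list with `time` and the neurons x time
#'   matrix `raster`.
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  tm <- as.numeric(strsplit(lines[1], "\t")[[1]][-1])
  rows <- strsplit(lines[-1], "\t")
  m <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
  rownames(m) <- vapply(rows, `[[`, character(1), 1L)
  list(time = tm, raster = m)
}
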