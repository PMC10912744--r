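#' Detect firings of the mean-field series
#'
#' A spike is registered at each upward threshold crossing (previous sample
#' below `threshold`, current sample at or above it) separated from the
#' previous accepted spike by at least `refractory` time units. The mean
#' field of an excitable FitzHugh-Nagumo network swings from a rest value
#' near -1 to spike peaks near +2, so the default threshold 0 cleanly
#' separates rest from firing; the default refractory period 1 is well below
#' the network's intrinsic firing period and cannot merge genuine
#' consecutive spikes.
#'
#' @param x numeric series (typically the mean field `X(t)`).
#' @param time time stamps of `x` (regular grid).
#' @param threshold crossing level (default 0).
#' @param refractory minimum spacing between accepted spikes (default 1).
#' @return numeric vector of spike times (possibly empty).
#' @export
detect_spikes <- function(x, time, threshold = 0, refractory = 1) {
  if (length(x) != length(time)) stop("x and time must have equal length")
  if (!all(is.finite(x))) stop("series contains non-finite values")
  if (refractory < 0) stop("refractory must be non-negative")
  n <- length(x)
  if (n < 2L) return(numeric(0))
  up <- which(x[-n] < threshold & x[-1L] >= threshold) + 1L
  if (!length(up)) return(numeric(0))
  st <- time[up]
  keep <- rep(FALSE, length(st))
  last <- -Inf
  for (i in seq_along(st)) {
    if (st[i] - last >= refractory) {
      keep[i] <- TRUE
      last <- st[i]
    }
  }
  st[keep]
}

#' Inter-spike intervals of a spike train
#'
#' Successive differences of the spike times. With fewer than two spikes the
#' result is empty.
#'
#' @param spikes numeric vector of strictly increasing spike times.
#' @return numeric vector of intervals (length `length(spikes) - 1`).
#' @export
extract_isis <- function(spikes) {
  if (length(spikes) < 2L) return(numeric(0))
  if (any(diff(spikes) <= 0)) stop("spike times must be strictly increasing")
  diff(spikes)
}

#' Accumulate mean-field inter-spike intervals over independent realizations
#'
#' Runs a per-realization recipe with incrementing seeds until at least
#' `L_target` intervals have been collected, concatenating the interval
#' series of the realizations. Intervals never span two realizations. The
#' result is truncated to exactly `L_target` intervals; if the realization
#' cap is reached first, the (short) series is returned with `no_firing`
#' set when nothing fired at all.
#'
#' @param recipe function taking a seed and returning the numeric ISI vector
#'   of one realization.
#' @param L_target number of intervals required (>= 1).
#' @param base_seed seed of the first realization; realization `r` uses
#'   `base_seed + r - 1`.
#' @param max_realizations cap on the number of realizations (default 100).
#' @param empty_limit stop early once this many consecutive realizations
#'   from the start have produced no interval at all (default 5): a
#'   condition silent over several independent realizations is a no-firing
#'   condition, and running out the full cap would waste the sweep budget.
#' @return An object of class `isi_series`: list with `intervals`,
#'   `realization` (provenance index per interval), `n_realizations`, and
#'   the `no_firing` flag.
#' @export
accumulate_isis <- function(recipe, L_target, base_seed = 1L,
                            max_realizations = 100L, empty_limit = 5L) {
  if (L_target < 1) stop("L_target must be at least 1")
  intervals <- list()
  prov <- list()
  total <- 0L
  r <- 0L
  while (total < L_target && r < max_realizations) {
    r <- r + 1L
    isi <- recipe(as.integer(base_seed) + r - 1L)
    if (length(isi)) {
      intervals[[r]] <- isi
      prov[[r]] <- rep.int(r, length(isi))
      total <- total + length(isi)
    } else if (total == 0L && r >= empty_limit) {
      break
    }
  }
  iv <- unlist(intervals, use.names = FALSE)
  pv <- unlist(prov, use.names = FALSE)
  if (is.null(iv)) { iv <- numeric(0); pv <- integer(0) }
  if (length(iv) > L_target) {
    iv <- iv[seq_len(L_target)]
    pv <- pv[seq_len(L_target)]
  }
  structure(list(intervals = iv, realization = pv, n_realizations = r,
                 no_firing = length(iv) == 0L),
            class = "isi_series")
}

#' @export
print.isi_series <- function(x, ...) {
  cat(sprintf("ISI series: L = %d from %d realization(s)%s\n",
              length(x$intervals), x$n_realizations,
              if (x$no_firing) " [no firing]" else ""))
  invisible(x)
}

#' Spikes-per-period histogram
#'
#' Partitions time into consecutive windows of length `Te` starting at the
#' first spike-train sample time and counts spikes per window. The modal
#' count identifies the firing class (period-1, period-2, ... firing:
#' one, two, ... spikes per drive period).
#'
#' @param spikes numeric spike times.
#' @param Te window length (the drive period).
#' @param t_start start of the first window; defaults to the first spike.
#' @param t_end end of the spanned interval; defaults to the last spike.
#' @return list with `counts` (spikes per complete window), `histogram`
#'   (table of counts), and `mode` (smallest modal count on ties).
#' @export
spikes_per_period <- function(spikes, Te, t_start = NULL, t_end = NULL) {
  stopifnot_scalar(Te, "Te", positive = TRUE)
  if (is.null(t_start)) t_start <- spikes[1]
  if (is.null(t_end)) t_end <- spikes[length(spikes)]
  n_win <- floor((t_end - t_start) / Te)
  if (is.na(n_win) || n_win < 2)
    stop("spike train must span at least 2 periods")
  idx <- floor((spikes - t_start) / Te)
  idx <- idx[idx >= 0 & idx < n_win]
  counts <- tabulate(idx + 1L, nbins = n_win)
  tab <- table(counts)
  mode <- as.integer(names(tab)[which.max(tab)])
  list(counts = counts, histogram = tab, mode = mode)
}

#' Write / read an interval series as single-column plain text
#'
#' One interval per line; provenance (seeds and realization boundaries) goes
#' to a JSON sidecar when `sidecar = TRUE`.
#'
#' @param isi an `isi_series` or bare numeric vector.
#' @param path output file.
#' @param sidecar write `<path>.json` with provenance.
#' @export
write_isi <- function(isi, path, sidecar = FALSE) {
  iv <- if (inherits(isi, "isi_series")) isi$intervals else as.numeric(isi)
  writeLines(sprintf("%.10g", iv), path)
  if (sidecar && inherits(isi, "isi_series")) {
    jsonlite::write_json(
      list(L = length(iv), n_realizations = isi$n_realizations,
           no_firing = isi$no_firing,
           realization_lengths = as.vector(table(isi$realization))),
      paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_isi
#' @return `read_isi` returns the numeric interval vector.
#' @export
read_isi <- function(path) {
  as.numeric(readLines(path))
}
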