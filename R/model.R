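#' Model parameters of the delay-coupled FitzHugh-Nagumo network
#'
#' Container for all parameters of the network equations
#' \deqn{\epsilon \dot x_i = x_i - x_i^3/3 - y_i
#'       + g \sum_j J_{ij} (x_j(t-\tau) - x_i(t))}
#' \deqn{\dot y_i = x_i + a + A \sin(2\pi t / T_e) + D \xi_i(t)}
#' with independent Gaussian white noise \eqn{\xi_i}. Defaults place each
#' neuron in the excitable regime (`|a| > 1`) driven by a subthreshold
#' periodic signal: without noise the signal alone never elicits a spike.
#'
#' @param eps time-scale ratio between the fast membrane variable and the
#'   slow recovery variable (default 0.01).
#' @param a excitability parameter; `|a| > 1` is the excitable regime
#'   (default 1.1).
#' @param A amplitude of the periodic drive (default 0.14, subthreshold).
#' @param Te period of the drive in time units (default 14).
#' @param g coupling strength (default 0.01).
#' @param D noise intensity (>= 0).
#' @param tau transmission delay in time units (>= 0).
#' @param sqrt2_noise logical; if `FALSE` (default) the discrete noise
#'   increment is `D * sqrt(dt) * eta` (amplitude convention, the literal
#'   reading of the model equation); if `TRUE` it is `sqrt(2 D dt) * eta`
#'   (intensity convention). See the methods vignette.
#' @return An object of class `fhn_params`.
#' @export
fhn_params <- function(eps = 0.01, a = 1.1, A = 0.14, Te = 14,
                       g = 0.01, D = 0.08, tau = 0, sqrt2_noise = FALSE) {
  stopifnot_scalar(eps, "eps", positive = TRUE)
  stopifnot_scalar(a, "a")
  stopifnot_scalar(A, "A")
  stopifnot_scalar(Te, "Te", positive = TRUE)
  stopifnot_scalar(g, "g")
  stopifnot_scalar(D, "D")
  stopifnot_scalar(tau, "tau")
  if (D < 0) stop("D must be non-negative")
  if (tau < 0) stop("tau must be non-negative")
  structure(list(eps = eps, a = a, A = A, Te = Te, g = g, D = D, tau = tau,
                 sqrt2_noise = isTRUE(sqrt2_noise)),
            class = "fhn_params")
}

#' Integration controls for the network simulation
#'
#' @param dt explicit Euler step (default 0.001 time units).
#' @param t_total simulated duration.
#' @param t_transient initial duration discarded before any output
#'   (default 100; large against the drive period so startup artifacts from
#'   the all-zero initial condition have decayed).
#' @param seed integer RNG seed for the noise stream.
#' @param record_stride subsampling factor for the optional per-neuron
#'   raster; the mean field is always recorded at full resolution.
#' @return An object of class `sim_control`.
#' @export
sim_control <- function(dt = 0.001, t_total = 500, t_transient = 100,
                        seed = 1L, record_stride = 10L) {
  stopifnot_scalar(dt, "dt", positive = TRUE)
  stopifnot_scalar(t_total, "t_total", positive = TRUE)
  stopifnot_scalar(t_transient, "t_transient")
  if (t_transient < 0 || t_transient >= t_total)
    stop("t_transient must lie in [0, t_total)")
  structure(list(dt = dt, t_total = t_total, t_transient = t_transient,
                 seed = as.integer(seed),
                 record_stride = as.integer(record_stride)),
            class = "sim_control")
}

#' Deterministic drift of the network equations
#'
#' Pure-R reference evaluation of the right-hand side (noise excluded), used
#' for rest-point analysis and as an independent check of the compiled
#' integrator.
#'
#' @param x,y state vectors of length `N`.
#' @param x_delayed delayed membrane potentials `x_j(t - tau)`, length `N`.
#' @param t current time.
#' @param model an [fhn_params()].
#' @param net a [ws_network()] (its adjacency provides the coupling matrix).
#' @return list with components `dx` and `dy`.
#' @export
fhn_drift <- function(x, y, x_delayed, t, model, net) {
  N <- net$N
  if (length(x) != N || length(y) != N || length(x_delayed) != N)
    stop("state vectors must have length N")
  deg <- rowSums(net$J)
  s <- as.vector(net$J %*% x_delayed)
  dx <- (x - x^3 / 3 - y + model$g * (s - deg * x)) / model$eps
  dy <- x + model$a + model$A * sin(2 * pi * t / model$Te)
  list(dx = dx, dy = dy)
}

#' Rest point of an uncoupled, undriven FitzHugh-Nagumo neuron
#'
#' Solves `x + a = 0` and `x - x^3/3 - y = 0`: the unique fixed point of the
#' drift with `A = 0`, `g = 0`.
#'
#' @param model an [fhn_params()].
#' @return list with components `x` and `y`.
#' @export
fhn_rest_point <- function(model) {
  x <- -model$a
  list(x = x, y = x - x^3 / 3)
}

#' Simulate the delay-coupled stochastic FitzHugh-Nagumo network
#'
#' Integrates the network equations with the explicit Euler(-Maruyama)
#' scheme: `x <- x + dt * dx`, `y <- y + dt * dy + amp * sqrt(dt) * eta`,
#' with `eta` an independent standard normal per neuron per step and `amp`
#' set by the noise convention in `model`. Initial values are
#' `x_i(0) = y_i(0) = 0` unless overridden; the delay history for `t < tau`
#' is the initial state. Identical seeds give bit-identical trajectories.
#'
#' @param net a [ws_network()].
#' @param model an [fhn_params()].
#' @param control a [sim_control()]. `tau` must be an integer multiple of
#'   `control$dt` within 1e-9.
#' @param x0,y0 optional initial states (scalar or length `N`); default 0.
#' @param raster logical; record the per-neuron membrane potentials at
#'   `control$record_stride` (memory permitting).
#' @return An object of class `fhn_trajectory`: list with `time`, mean-field
#'   series `X`, optional `raster` (time x neuron matrix) and `raster_time`,
#'   final states, and the generating parameters.
#' @examples
#' net <- ws_network(50, 10, 0.15, seed = 1)
#' tr <- simulate_fhn(net, fhn_params(D = 0.08),
#'                    sim_control(t_total = 150, t_transient = 50, seed = 1))
#' range(tr$X)
#' @export
simulate_fhn <- function(net, model, control, x0 = 0, y0 = 0, raster = FALSE) {
  stopifnot(inherits(net, "ws_network"), inherits(model, "fhn_params"),
            inherits(control, "sim_control"))
  H <- round(model$tau / control$dt)
  if (abs(H * control$dt - model$tau) > 1e-9)
    stop("tau must be an integer multiple of dt (tolerance 1e-9)")
  res <- fhn_integrate_cpp(
    edges = net$edges - 1L, N = net$N,
    eps = model$eps, a = model$a, A = model$A, Te = model$Te,
    g = model$g, D = model$D, tau = model$tau,
    dt = control$dt, t_total = control$t_total,
    t_transient = control$t_transient,
    seed = control$seed, sqrt2_noise = model$sqrt2_noise,
    x0 = as.numeric(x0), y0 = as.numeric(y0),
    record_stride = control$record_stride, record_raster = raster)
  structure(c(res, list(dt = control$dt, net = net, model = model,
                        control = control)),
            class = "fhn_trajectory")
}

#' @export
print.fhn_trajectory <- function(x, ...) {
  cat(sprintf(
    "FHN network trajectory: N = %d, D = %g, tau = %g, %d samples on [%.6g, %.6g]\n",
    x$net$N, x$model$D, x$model$tau, length(x$X), x$time[1],
    x$time[length(x$time)]))
  invisible(x)
}

#' Mean field of a membrane-potential raster
#'
#' Arithmetic mean over neurons at each recorded time point.
#'
#' @param raster numeric matrix, time points in rows, neurons in columns.
#' @return numeric vector of row means.
#' @export
mean_field <- function(raster) {
  if (is.null(dim(raster))) raster <- matrix(raster, ncol = 1)
  if (nrow(raster) == 0L || ncol(raster) == 0L) stop("empty raster")
  rowMeans(raster)
}

#' Write a trajectory to CSV
#'
#' Columns `time,X`, plus `x0..x{N-1}` at the raster time points when the
#' per-neuron raster was recorded (written as a separate file suffix `_raster`
#' would lose alignment, so raster output uses [export_raster()] instead).
#'
#' @param traj an `fhn_trajectory`.
#' @param path output CSV file.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(time = traj$time, X = traj$X)
  utils::write.csv(format(df, digits = 10, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
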