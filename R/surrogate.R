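# Surrogate interval-series generators. These emulate the statistical
# structure of mean-field ISI sequences -- cyclic firing patterns with
# jitter, and structureless i.i.d. intervals -- so the ordinal-complexity
# stages can be exercised and validated without running the network
# simulator.

# truncated-Gaussian draw: reject non-positive values, redraw
rtnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= 0)
  guard <- 0L
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= 0]
    guard <- guard + 1L
    if (guard > 10000L) stop("truncated-Gaussian rejection failed to converge")
  }
  out
}

#' Surrogate periodic interval series
#'
#' Cyclic repetition of a base interval pattern with i.i.d. truncated-
#' Gaussian jitter on each interval. A pattern of `k` intervals summing to
#' the drive period emulates period-k firing (k spikes per drive cycle).
#'
#' @param pattern base intervals (all > 0), repeated cyclically.
#' @param jitter_sd standard deviation of the Gaussian jitter (>= 0);
#'   draws are rejected until positive so intervals stay > 0.
#' @param L series length.
#' @param seed RNG seed (deterministic output for a given seed).
#' @return numeric interval vector of length `L`.
#' @examples
#' generate_periodic_isi(c(4, 10), jitter_sd = 0, L = 6)
#' @export
generate_periodic_isi <- function(pattern, jitter_sd = 0, L = 1000L, seed = NULL) {
  if (!length(pattern) || any(!is.finite(pattern)) || any(pattern <= 0))
    stop("pattern intervals must be positive and finite")
  if (jitter_sd < 0) stop("jitter_sd must be non-negative")
  base <- rep_len(pattern, L)
  if (jitter_sd == 0) return(base)
  with_seed(seed, {
    jit <- stats::rnorm(L, 0, jitter_sd)
    out <- base + jit
    bad <- which(out <= 0)
    guard <- 0L
    while (length(bad)) {
      out[bad] <- base[bad] + stats::rnorm(length(bad), 0, jitter_sd)
      bad <- bad[out[bad] <= 0]
      guard <- guard + 1L
      if (guard > 10000L) stop("jitter rejection failed to converge")
    }
    out
  })
}

#' Surrogate i.i.d. interval series
#'
#' Independent truncated-Gaussian (positive) intervals: the structureless
#' null model against which patterned firing is discriminated.
#'
#' @param mean interval mean (> 0).
#' @param sd interval standard deviation (>= 0).
#' @param L series length.
#' @param seed RNG seed.
#' @return numeric interval vector of length `L`.
#' @export
generate_iid_isi <- function(mean, sd, L = 1000L, seed = NULL) {
  stopifnot_scalar(mean, "mean", positive = TRUE)
  if (sd < 0) stop("sd must be non-negative")
  with_seed(seed, rtnorm_pos(L, mean, sd))
}
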