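# Internal helpers shared across the package.

# Evaluate `code` under a locally seeded R RNG, restoring the caller's
# .Random.seed afterwards. seed = NULL leaves the global stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic per-condition seed derived from a base seed, the control value
# and a realization index. Adding grid points never changes the seed of an
# existing condition. Result is a positive integer below 2^31 - 1.
condition_seed <- function(base_seed, value, realization = 0L) {
  p <- 2147483647
  v <- abs(round(value * 1e6)) %% p
  h <- (as.numeric(base_seed) %% p)
  h <- (h * 31 + v) %% p
  h <- (h * 37 + as.numeric(realization)) %% p
  as.integer(h %% (p - 1) + 1)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}
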