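# Shared fixtures and independent oracles used across test files.

# the six-interval worked series used throughout the ordinal tests
worked_series <- c(1.1, 3.5, 2.3, 4.7, 1.8, 5.6)

# brute-force ordinal pattern: stable argsort by (value, index)
oracle_pattern <- function(w) {
  ord <- order(w, seq_along(w)) # ties broken by temporal index
  as.integer(ord - 1L)
}

# brute-force pattern distribution via string tabulation
oracle_distribution <- function(x, d) {
  n <- length(x) - d + 1L
  pats <- vapply(seq_len(n), function(i) {
    paste(oracle_pattern(x[i:(i + d - 1L)]), collapse = ",")
  }, character(1))
  all_p <- apply(fhnsmr:::lex_permutations(d), 1, paste, collapse = ",")
  as.vector(table(factor(pats, levels = all_p))) / n
}

# small default network reused by simulator tests (cheap to build)
small_net <- function(N = 50, k = 10, p = 0.15, seed = 7) {
  ws_network(N, k, p, seed = seed)
}

# one-step explicit Euler reference in pure R (no noise)
r_euler_step <- function(x, y, xd, t, dt, model, net) {
  dr <- fhn_drift(x, y, xd, t, model, net)
  list(x = x + dt * dr$dx, y = y + dt * dr$dy)
}
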