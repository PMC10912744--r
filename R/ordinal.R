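#' Ordinal (Bandt-Pompe) pattern of a window
#'
#' Returns the permutation of `0..d-1` giving the positions of the window's
#' elements in ascending value order. Ties are broken by temporal order
#' (smaller index first), the standard stable convention in ordinal
#' time-series analysis. For example `{1.1, 3.5, 2.3}` maps to `(0, 2, 1)`:
#' position 0 holds the smallest value, then position 2, then position 1.
#'
#' @param window numeric vector of length `d`.
#' @return integer permutation of `0:(d-1)`.
#' @export
ordinal_pattern <- function(window) {
  if (!is.numeric(window) || length(window) < 2L)
    stop("window must be a numeric vector of length >= 2")
  order(window, method = "radix") - 1L
}

# All permutations of 0..d-1 in lexicographic order, one per row.
lex_permutations <- function(d) {
  if (d == 1L) return(matrix(0L, 1, 1))
  sub <- lex_permutations(d - 1L)
  out <- matrix(0L, factorial(d), d)
  m <- nrow(sub)
  for (first in 0:(d - 1L)) {
    rest <- setdiff(0:(d - 1L), first)
    out[(first * m + 1):((first + 1) * m), 1] <- first
    out[(first * m + 1):((first + 1) * m), -1] <- matrix(rest[sub + 1L], m)
  }
  out
}

# Lexicographic rank (1-based) of each row of a 0-based permutation matrix,
# via the Lehmer code: rank = 1 + sum_k c_k (d-1-k)! with
# c_k = #{l > k : pi_l < pi_k}.
perm_lex_rank <- function(pi_mat) {
  d <- ncol(pi_mat)
  r <- rep(0, nrow(pi_mat))
  for (k in seq_len(d - 1L)) {
    c_k <- rep(0L, nrow(pi_mat))
    for (l in (k + 1L):d) c_k <- c_k + (pi_mat[, l] < pi_mat[, k])
    r <- r + c_k * factorial(d - k)
  }
  as.integer(r + 1L)
}

#' Bandt-Pompe ordinal-pattern probability distribution
#'
#' Slides a window of length `d` with unit stride over the series and counts
#' the ordinal pattern of each of the `L - d + 1` windows; `p(pi)` is the
#' relative frequency of permutation `pi`. Probabilities are indexed in
#' lexicographic order of the permutations.
#'
#' @param x numeric series of length `L >= d`.
#' @param d embedding dimension, `3 <= d <= 7`. Reliable estimation wants
#'   `L >> d!`; a warning is issued below `100 * d!` windows.
#' @param warn logical; emit the short-series warning (default TRUE).
#' @return An object of class `ordinal_distribution`: list with `d`,
#'   `M = d!`, `probs` (length `M`, lexicographic order), `counts`,
#'   `n_windows`, and `patterns` (the `M x d` permutation table).
#' @examples
#' pattern_distribution(c(1.1, 3.5, 2.3, 4.7, 1.8, 5.6), d = 3)$probs
#' @export
pattern_distribution <- function(x, d = 3L, warn = TRUE) {
  d <- as.integer(d)
  if (d < 3L || d > 7L) stop("d must lie in 3..7")
  L <- length(x)
  if (L < d) stop("series shorter than the embedding dimension")
  M <- factorial(d)
  n <- L - d + 1L
  if (warn && n < 100 * M)
    warning(sprintf("only %d windows for %d patterns; L >> d! is advised", n, M))

  # embed() rows run backwards in time; reverse to temporal order
  W <- stats::embed(x, d)[, d:1, drop = FALSE]

  # value ranks with ties broken by temporal index:
  # rho_i = 1 + #{j : w_j < w_i} + #{j < i : w_j == w_i}
  rho <- matrix(0L, n, d)
  for (i in seq_len(d)) {
    ri <- rep(1L, n)
    for (j in seq_len(d)) {
      if (j == i) next
      if (j < i) ri <- ri + (W[, j] <= W[, i])
      else       ri <- ri + (W[, j] <  W[, i])
    }
    rho[, i] <- ri
  }
  # pattern pi = order(window): pi[rho_i] = i - 1
  pi_mat <- matrix(0L, n, d)
  for (i in seq_len(d)) pi_mat[cbind(seq_len(n), rho[, i])] <- i - 1L

  counts <- tabulate(perm_lex_rank(pi_mat), nbins = M)
  structure(list(d = d, M = M, probs = counts / n, counts = counts,
                 n_windows = n, patterns = lex_permutations(d)),
            class = "ordinal_distribution")
}

#' @export
print.ordinal_distribution <- function(x, ...) {
  cat(sprintf("Ordinal distribution: d = %d (%d patterns), %d windows\n",
              x$d, x$M, x$n_windows))
  nz <- which(x$probs > 0)
  lab <- apply(x$patterns[nz, , drop = FALSE], 1,
               function(p) paste0("(", paste(p, collapse = ","), ")"))
  for (i in seq_along(nz))
    cat(sprintf("  %s  %.6g\n", lab[i], x$probs[nz[i]]))
  invisible(x)
}

check_distribution <- function(P, tol = 1e-9) {
  p <- if (inherits(P, "ordinal_distribution")) P$probs else as.numeric(P)
  if (any(p < -tol)) stop("negative probabilities")
  if (abs(sum(p) - 1) > tol) stop("probabilities must sum to 1")
  pmax(p, 0)
}

#' Shannon entropy of a probability distribution (nats)
#'
#' `S[P] = -sum p_i ln p_i`, with the convention `0 ln 0 = 0`.
#'
#' @param P probability vector or `ordinal_distribution` (must sum to 1
#'   within 1e-9).
#' @return entropy in nats, in `[0, ln M]`.
#' @export
shannon_entropy <- function(P) {
  p <- check_distribution(P)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Normalized Shannon entropy (NSE)
#'
#' `H[P] = S[P] / ln M`, the Shannon entropy relative to its maximum over
#' `M` outcomes. 1 for the uniform distribution, 0 for a point mass.
#'
#' @inheritParams shannon_entropy
#' @return value in `[0, 1]`.
#' @export
nse <- function(P) {
  p <- check_distribution(P)
  shannon_entropy(p) / log(length(p))
}

#' Jensen-Shannon divergence from the uniform distribution
#'
#' `J[P, Pe] = S[(P + Pe)/2] - S[P]/2 - S[Pe]/2` with `Pe` uniform over the
#' same `M` outcomes. Non-negative; zero iff `P = Pe`.
#'
#' @inheritParams shannon_entropy
#' @return divergence in nats.
#' @export
jensen_shannon <- function(P) {
  p <- check_distribution(P)
  M <- length(p)
  pe <- rep(1 / M, M)
  shannon_entropy((p + pe) / 2) - shannon_entropy(p) / 2 - shannon_entropy(pe) / 2
}

#' Disequilibrium (normalized Jensen-Shannon divergence)
#'
#' `Q[P] = Q0 * J[P, Pe]` with
#' `Q0 = -2 / (((M+1)/M) ln(M+1) - 2 ln(2M) + ln M)`, the constant that
#' makes the divergence between a point mass and the uniform distribution
#' exactly 1.
#'
#' @inheritParams shannon_entropy
#' @return value in `[0, 1]`.
#' @export
disequilibrium <- function(P) {
  p <- check_distribution(P)
  M <- length(p)
  Q0 <- -2 / (((M + 1) / M) * log(M + 1) - 2 * log(2 * M) + log(M))
  Q0 * jensen_shannon(p)
}

#' Statistical complexity measure (SCM)
#'
#' `C[P] = H[P] * Q[P]`: the product of the normalized Shannon entropy and
#' the disequilibrium. Vanishes at both extremes (uniform: Q = 0; point
#' mass: H = 0) and is positive for structured-but-nontrivial distributions,
#' which is what makes it a sensitive detector of resonant, patterned firing.
#'
#' @inheritParams shannon_entropy
#' @param no_firing logical flag carried through to the summary.
#' @return An object of class `complexity_summary`: list with `S` (entropy,
#'   nats), `H` (NSE), `Q` (disequilibrium), `C = H * Q`, and `no_firing`.
#' @export
scm <- function(P, no_firing = FALSE) {
  p <- check_distribution(P)
  S <- shannon_entropy(p)
  H <- S / log(length(p))
  Q <- disequilibrium(p)
  structure(list(S = S, H = H, Q = Q, C = H * Q, no_firing = no_firing,
                 M = length(p)),
            class = "complexity_summary")
}

#' @export
print.complexity_summary <- function(x, ...) {
  cat(sprintf("S = %.6g nats, NSE = %.6g, Q = %.6g, SCM = %.6g%s\n",
              x$S, x$H, x$Q, x$C, if (x$no_firing) " [no firing]" else ""))
  invisible(x)
}

#' Statistical complexity of an interval series
#'
#' Full ordinal-complexity pipeline for a (possibly empty) mean-field ISI
#' series: ordinal-pattern distribution at embedding dimension `d`, then
#' NSE and SCM. A series too short to embed (fewer than `d` intervals,
#' including the no-firing case) is reported with the convention
#' `SCM = 0`, `NSE = 1`: an unobservable firing pattern is treated as
#' maximally disordered and structureless.
#'
#' @param isi an `isi_series` or numeric interval vector.
#' @param d embedding dimension (default 3).
#' @param warn pass-through to [pattern_distribution()].
#' @return a `complexity_summary`.
#' @export
complexity_of_isi <- function(isi, d = 3L, warn = FALSE) {
  iv <- if (inherits(isi, "isi_series")) isi$intervals else as.numeric(isi)
  flagged <- inherits(isi, "isi_series") && isi$no_firing
  if (flagged || length(iv) < d) {
    return(structure(list(S = NA_real_, H = 1, Q = NA_real_, C = 0,
                          no_firing = TRUE, M = factorial(as.integer(d))),
                     class = "complexity_summary"))
  }
  scm(pattern_distribution(iv, d = d, warn = warn))
}
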