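#' Build a Watts-Strogatz small-world coupling network
#'
#' Constructs the symmetric binary adjacency of a Watts-Strogatz graph: a ring
#' lattice of `N` nodes each linked to its `k` nearest neighbours (`k/2` on
#' each side), followed by random rewiring. Each ring edge `(i, i + offset)`
#' is, with probability `p`, replaced by an edge from `i` to a uniformly
#' chosen node, rejecting self-loops and duplicate edges. Rewiring therefore
#' preserves the edge count `N * k / 2` exactly.
#'
#' @param N number of neurons (positive integer).
#' @param k nearest-neighbour degree of the initial ring (even, `k < N`).
#' @param p rewiring probability in `[0, 1]`.
#' @param seed integer seed making the rewiring reproducible; `NULL` uses the
#'   current RNG state.
#' @return An object of class `ws_network`: a list with the adjacency `J`
#'   (`N x N` 0/1 matrix, zero diagonal), the edge list `edges` (`E x 2`
#'   integer matrix, 1-based), and the generating parameters.
#' @examples
#' net <- ws_network(100, 30, 0.15, seed = 1)
#' sum(net$J) / 2  # N * k / 2 edges
#' @export
ws_network <- function(N, k, p, seed = NULL) {
  stopifnot_scalar(N, "N", positive = TRUE)
  stopifnot_scalar(k, "k", positive = TRUE)
  stopifnot_scalar(p, "p")
  N <- as.integer(N); k <- as.integer(k)
  if (k >= N) stop("k must be smaller than N")
  if (k %% 2L != 0L) stop("k must be even")
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")

  J <- matrix(0L, N, N)
  for (off in seq_len(k %/% 2L)) {
    i <- seq_len(N)
    j <- (i - 1L + off) %% N + 1L
    J[cbind(i, j)] <- 1L
    J[cbind(j, i)] <- 1L
  }

  if (p > 0) {
    with_seed(seed, {
      for (off in seq_len(k %/% 2L)) {
        for (i in seq_len(N)) {
          if (stats::runif(1) >= p) next
          j <- (i - 1L + off) %% N + 1L
          if (!J[i, j]) next            # already rewired away by an earlier pass
          # candidate new endpoints: not i, not already linked to i
          free <- which(J[i, ] == 0L)
          free <- free[free != i]
          if (!length(free)) next        # node saturated; keep the ring edge
          m <- if (length(free) == 1L) free else free[sample.int(length(free), 1L)]
          J[i, j] <- 0L; J[j, i] <- 0L
          J[i, m] <- 1L; J[m, i] <- 1L
        }
      }
    })
  }

  up <- which(upper.tri(J) & J == 1L, arr.ind = TRUE)
  structure(
    list(J = J, edges = unname(up), N = N, k = k, p = p, seed = seed),
    class = "ws_network"
  )
}

#' @export
print.ws_network <- function(x, ...) {
  cat(sprintf("Watts-Strogatz network: N = %d, k = %d, p = %g, %d edges\n",
              x$N, x$k, x$p, nrow(x$edges)))
  invisible(x)
}

#' Node degrees of a network
#' @param net a `ws_network`.
#' @return integer vector of length `N`.
#' @export
network_degrees <- function(net) {
  as.integer(rowSums(net$J))
}

#' Write / read a network as a plain-text edge list
#'
#' The file holds one 0-based node pair per line, preceded by a single header
#' comment line `# N k p seed` recording the generating parameters.
#'
#' @param net a `ws_network`.
#' @param path output file.
#' @export
write_edgelist <- function(net, path) {
  seed <- if (is.null(net$seed)) "NA" else format(net$seed)
  header <- sprintf("# %d %d %.10g %s", net$N, net$k, net$p, seed)
  body <- sprintf("%d %d", net$edges[, 1] - 1L, net$edges[, 2] - 1L)
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_edgelist
#' @return `read_edgelist` returns a `ws_network` rebuilt from the file.
#' @export
read_edgelist <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(sub("^#\\s*", "", lines[1]), "\\s+")[[1]]
  N <- as.integer(hdr[1]); k <- as.integer(hdr[2]); p <- as.numeric(hdr[3])
  seed <- suppressWarnings(as.integer(hdr[4]))
  pairs <- do.call(rbind, lapply(strsplit(lines[-1], "\\s+"), as.integer)) + 1L
  J <- matrix(0L, N, N)
  J[pairs] <- 1L
  J[pairs[, 2:1, drop = FALSE]] <- 1L
  up <- which(upper.tri(J) & J == 1L, arr.ind = TRUE)
  structure(
    list(J = J, edges = unname(up), N = N, k = k, p = p,
         seed = if (is.na(seed)) NULL else seed),
    class = "ws_network"
  )
}
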