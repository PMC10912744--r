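# Bandt-Pompe ordinal patterns, the pattern distribution, and the
# entropy/disequilibrium/complexity quantifiers.

test_that("ordinal patterns of the worked three-element windows are exact", {
  expect_identical(ordinal_pattern(c(1.1, 3.5, 2.3)), c(0L, 2L, 1L))
  expect_identical(ordinal_pattern(c(3.5, 2.3, 4.7)), c(1L, 0L, 2L))
  expect_identical(ordinal_pattern(c(2.3, 4.7, 1.8)), c(2L, 0L, 1L))
  expect_identical(ordinal_pattern(c(4.7, 1.8, 5.6)), c(1L, 0L, 2L))
})

test_that("ordinal_pattern matches a stable-argsort oracle on all 4^3 windows", {
  vals <- c(0.5, 1.5, 2.5, 3.5)
  grid <- expand.grid(a = vals, b = vals, c = vals)
  for (i in seq_len(nrow(grid))) {
    w <- as.numeric(grid[i, ])
    expect_identical(ordinal_pattern(w), oracle_pattern(w))
  }
})

test_that("ties are broken by temporal order", {
  expect_identical(ordinal_pattern(c(2, 2, 2)), c(0L, 1L, 2L))
  expect_identical(ordinal_pattern(c(2, 1, 1)), c(1L, 2L, 0L))
})

test_that("pattern distribution reproduces the worked six-element example", {
  pd <- pattern_distribution(worked_series, d = 3, warn = FALSE)
  expect_equal(pd$probs, c(0, 1/4, 2/4, 0, 1/4, 0))
  expect_identical(pd$n_windows, 4L)
  expect_identical(sum(pd$counts), pd$n_windows)
})

test_that("pattern distribution matches the brute-force oracle on random series", {
  set.seed(42)
  for (d in 3:5) {
    x <- rnorm(200)
    pd <- pattern_distribution(x, d = d, warn = FALSE)
    expect_equal(pd$probs, oracle_distribution(x, d))
    expect_identical(sum(pd$counts), length(x) - d + 1L)
    expect_equal(sum(pd$probs), 1, tolerance = 1e-12)
  }
})

test_that("degenerate series map to single patterns", {
  inc <- pattern_distribution(sort(rnorm(50)), d = 3, warn = FALSE)
  expect_equal(inc$probs[1], 1)  # (0,1,2) first in lexicographic order
  const <- pattern_distribution(rep(1, 50), d = 3, warn = FALSE)
  expect_equal(const$probs[1], 1)  # temporal tie-break: also (0,1,2)
})

test_that("input validation rejects bad windows and dimensions", {
  expect_error(pattern_distribution(1:2, d = 3), "shorter")
  expect_error(pattern_distribution(rnorm(50), d = 2), "3..7", fixed = TRUE)
  expect_error(pattern_distribution(rnorm(50), d = 8), "3..7", fixed = TRUE)
  expect_warning(pattern_distribution(rnorm(20), d = 3), "windows")
})

test_that("Shannon entropy has its closed-form values at the extremes", {
  expect_equal(shannon_entropy(rep(1/6, 6)), log(6), tolerance = 1e-12)
  expect_equal(shannon_entropy(c(1, rep(0, 5))), 0)
  # the worked distribution, evaluated by hand
  expect_equal(shannon_entropy(c(0, 1/4, 1/2, 0, 1/4, 0)),
               -(0.25 * log(0.25) * 2 + 0.5 * log(0.5)), tolerance = 1e-12)
  expect_error(shannon_entropy(c(0.5, 0.4)), "sum to 1")
})

test_that("NSE is 1 for uniform, 0 for delta, and S/ln M in between", {
  expect_equal(nse(rep(1/6, 6)), 1, tolerance = 1e-12)
  expect_equal(nse(c(1, rep(0, 5))), 0)
  S <- -(0.25 * log(0.25) * 2 + 0.5 * log(0.5))
  expect_equal(nse(c(0, 1/4, 1/2, 0, 1/4, 0)), S / log(6), tolerance = 1e-12)
})

test_that("Jensen-Shannon divergence: zero at uniform, closed form at delta", {
  M <- 6
  pe <- rep(1/M, M)
  expect_equal(jensen_shannon(pe), 0, tolerance = 1e-12)
  delta <- c(1, rep(0, M - 1))
  # direct evaluation of S[(P+Pe)/2] - S[P]/2 - S[Pe]/2 for the point mass
  mid <- (delta + pe) / 2
  expected <- -sum(mid[mid > 0] * log(mid[mid > 0])) - 0 / 2 - log(M) / 2
  expect_equal(jensen_shannon(delta), expected, tolerance = 1e-12)
  expect_gt(jensen_shannon(delta), 0)
})

test_that("disequilibrium normalizer maps the point mass to exactly 1", {
  for (d in 3:7) {
    M <- factorial(d)
    expect_equal(disequilibrium(c(1, rep(0, M - 1))), 1, tolerance = 1e-9)
    expect_equal(disequilibrium(rep(1/M, M)), 0, tolerance = 1e-12)
  }
  # Q0 at M = 6 by direct substitution, frozen as a regression constant
  Q0 <- -2 / ((7/6) * log(7) - 2 * log(12) + log(6))
  delta <- c(1, rep(0, 5))
  expect_equal(disequilibrium(delta), Q0 * jensen_shannon(delta),
               tolerance = 1e-12)
})

test_that("SCM vanishes at both extremes and equals H*Q in between", {
  M <- 6
  uni <- scm(rep(1/M, M))
  expect_equal(uni$C, 0, tolerance = 1e-12)
  expect_equal(uni$H, 1, tolerance = 1e-12)
  del <- scm(c(1, rep(0, M - 1)))
  expect_equal(del$C, 0)
  expect_equal(del$Q, 1, tolerance = 1e-9)
  pd <- pattern_distribution(worked_series, d = 3, warn = FALSE)
  cs <- scm(pd)
  expect_equal(cs$C, cs$H * cs$Q, tolerance = 1e-15)
  expect_equal(cs$H, nse(pd$probs), tolerance = 1e-15)
  expect_equal(cs$Q, disequilibrium(pd$probs), tolerance = 1e-15)
  expect_gt(cs$C, 0)
})

test_that("H, Q, C stay within [0,1] on random distributions", {
  set.seed(11)
  for (i in 1:50) {
    p <- rexp(24); p <- p / sum(p)
    cs <- scm(p)
    expect_true(cs$H >= 0 && cs$H <= 1)
    expect_true(cs$Q >= 0 && cs$Q <= 1)
    expect_true(cs$C >= 0 && cs$C <= 1)
    expect_gt(cs$C, 0)  # neither uniform nor delta almost surely
  }
})

test_that("complexity_of_isi applies the no-firing convention", {
  empty <- complexity_of_isi(numeric(0))
  expect_equal(empty$C, 0)
  expect_equal(empty$H, 1)
  expect_true(empty$no_firing)
  short <- complexity_of_isi(c(3.4, 3.5))  # below the embedding dimension
  expect_true(short$no_firing)
  expect_equal(short$C, 0)

  cs <- complexity_of_isi(worked_series, d = 3)
  ref <- scm(pattern_distribution(worked_series, d = 3, warn = FALSE))
  expect_equal(cs$C, ref$C)
  expect_false(cs$no_firing)
})

test_that("a long i.i.d. series is nearly maximally entropic", {
  set.seed(99)
  x <- runif(50000)
  cs <- complexity_of_isi(x, d = 3)
  expect_gt(cs$H, 0.99)
  expect_lt(cs$C, 0.02)
})
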