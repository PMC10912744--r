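# Sweep protocols, extrema detection, intrinsic period, raster export.
# Simulator-heavy checks live in test-acceptance.R; here the sweep logic is
# exercised mostly through cheap conditions and synthetic curves.

test_that("local extrema match a brute-force neighbour scan", {
  brute <- function(y) {
    n <- length(y)
    i <- 2:(n - 1)
    list(maxima = i[y[i] > y[i - 1] & y[i] > y[i + 1]],
         minima = i[y[i] < y[i - 1] & y[i] < y[i + 1]])
  }
  set.seed(14)
  for (r in 1:20) {
    y <- rnorm(30)
    got <- find_local_extrema(y, prominence = 0)
    ref <- brute(y)
    expect_identical(got$maxima, ref$maxima)
    expect_identical(got$minima, ref$minima)
  }
})

test_that("extrema detection handles canonical shapes", {
  expect_length(find_local_extrema(1:10)$maxima, 0)      # monotone
  e <- find_local_extrema(c(0, 1, 0, 2, 0))
  expect_identical(e$maxima, c(2L, 4L))
  expect_identical(e$minima, 3L)
  flat <- find_local_extrema(rep(1, 5))
  expect_length(flat$maxima, 0)
  expect_error(find_local_extrema(c(1, 2)), "3 points")
})

test_that("the prominence filter removes shallow wiggles", {
  y <- c(0, 1, 0.98, 1.01, 0, 0.5, 0)
  # with no prominence requirement both little peaks count
  expect_length(find_local_extrema(y, prominence = 0)$maxima, 3)
  # requiring 10% of range keeps only the substantial ones
  e <- find_local_extrema(y, prominence = 0.1)
  expect_identical(e$maxima, c(4L, 6L))
})

test_that("predicted resonance count follows the period-ratio rule", {
  expect_identical(predicted_resonance_count(14, 3.45), 4L)
  expect_identical(predicted_resonance_count(5, 10), 0L)
  # off-boundary pairs agree with the floor-division oracle
  set.seed(17)
  for (r in 1:50) {
    Te <- runif(1, 1, 50); T0 <- runif(1, 1, 10)
    if (abs(Te / T0 - round(Te / T0)) < 1e-9) next
    expect_identical(predicted_resonance_count(Te, T0),
                     as.integer(Te %/% T0))
  }
  # boundary resolves downward: Te = m*T0 gives m
  expect_identical(predicted_resonance_count(10, 2.5), 4L)
  expect_error(predicted_resonance_count(-1, 2), "positive")
})

test_that("the delay and noise grids contain the distinguished values", {
  dg <- default_delay_grid()
  expect_true(all(seq(14, 98, by = 14) %in% dg))
  ng <- default_noise_grid()
  expect_true(all(c(0.001, 0.02, 0.04, 0.065, 0.08, 0.14) %in% ng))
  expect_true(min(ng) <= 0.0005 + 1e-9 && max(ng) >= 0.2 - 1e-9)
  expect_false(is.unsorted(ng))
})

test_that("run_condition propagates the no-firing convention at D = 0", {
  net <- small_net(30, 6, 0.15, seed = 1)
  res <- run_condition(net, fhn_params(D = 0),
                       sim_control(t_total = 30, t_transient = 10, seed = 1),
                       L_target = 50, max_realizations = 3)
  expect_true(res$complexity$no_firing)
  expect_equal(res$complexity$C, 0)
  expect_equal(res$complexity$H, 1)
})

test_that("run_condition is deterministic given the seed policy", {
  net <- small_net(30, 6, 0.15, seed = 1)
  ctl <- sim_control(t_total = 60, t_transient = 10, seed = 3)
  a <- run_condition(net, fhn_params(D = 0.1), ctl, L_target = 20,
                     max_realizations = 5)
  b <- run_condition(net, fhn_params(D = 0.1), ctl, L_target = 20,
                     max_realizations = 5)
  expect_identical(a$complexity$C, b$complexity$C)
  expect_identical(a$isi$intervals, b$isi$intervals)
})

test_that("sweep results are independent of grid order", {
  net <- small_net(30, 6, 0.15, seed = 1)
  ctl <- sim_control(t_total = 60, t_transient = 10, seed = 3)
  model <- fhn_params()
  vals <- c(0.05, 0.1, 0.15)
  fwd <- sweep_resonance("D", vals, net, model, ctl, L_target = 20,
                         max_realizations = 4)
  rev <- sweep_resonance("D", rev(vals), net, model, ctl, L_target = 20,
                         max_realizations = 4)
  expect_equal(as.data.frame(fwd), as.data.frame(rev))
})

test_that("sweeps over network parameters rebuild the network", {
  ctl <- sim_control(t_total = 40, t_transient = 10, seed = 2)
  net <- small_net(20, 4, 0.1, seed = 1)
  cv <- sweep_resonance("N", c(20, 30, 40), net, fhn_params(D = 0.1), ctl,
                        L_target = 10, max_realizations = 3)
  expect_equal(cv$control, c(20, 30, 40))
  expect_true(all(is.finite(cv$C)))
})

test_that("intrinsic period estimation recovers an injected uniform train", {
  # inject a surrogate recipe through accumulate_isis, then take the
  # histogram mode exactly as estimate_intrinsic_period does
  isi <- accumulate_isis(function(seed) rep(3.45, 50), L_target = 500)
  iv <- isi$intervals
  breaks <- seq(0, ceiling(max(iv) / 0.1) * 0.1 + 0.1, by = 0.1)
  h <- hist(iv, breaks = breaks, plot = FALSE)
  expect_equal(h$mids[which.max(h$counts)], 3.45)
})

test_that("intrinsic period estimation fails without firing", {
  net <- small_net(20, 4, 0.1, seed = 1)
  expect_error(
    estimate_intrinsic_period(net, fhn_params(D = 0),
                              sim_control(t_total = 30, t_transient = 10,
                                          seed = 1),
                              n_isi = 100, max_realizations = 3),
    "firing")
})

test_that("rasters round-trip through the TSV space-time format", {
  net <- small_net(12, 4, 0.1, seed = 2)
  tr <- simulate_fhn(net, fhn_params(D = 0.05),
                     sim_control(t_total = 3, t_transient = 1, seed = 5,
                                 record_stride = 20L),
                     raster = TRUE)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_raster(tr, path)
  back <- read_raster(path)
  expect_equal(back$time, tr$raster_time, tolerance = 1e-9)
  expect_equal(unname(back$raster), unname(t(tr$raster)), tolerance = 1e-9)
  expect_identical(rownames(back$raster), sprintf("x%d", 0:11))
  # trajectories without rasters refuse to export
  tr2 <- simulate_fhn(net, fhn_params(D = 0.05),
                      sim_control(t_total = 3, t_transient = 1, seed = 5))
  expect_error(export_raster(tr2, path), "raster")
})

test_that("condition seeds are stable under grid extension", {
  s1 <- fhnsmr:::condition_seed(1, 0.04)
  s2 <- fhnsmr:::condition_seed(1, 0.04)
  expect_identical(s1, s2)
  expect_false(identical(s1, fhnsmr:::condition_seed(1, 0.08)))
  expect_false(identical(s1, fhnsmr:::condition_seed(2, 0.04)))
  expect_true(s1 >= 1 && s1 < 2^31)
})
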