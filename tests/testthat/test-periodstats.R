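test_that("noiseless peaks and crossings are spaced by one period", {
  p <- phase_params(epsilon = 0)
  f <- fourier_regfun(0, 1)
  traj <- simulate_phase_output(p, f, duration = 12)
  pk <- detect_peaks(traj, discard_before = 2)
  expect_equal(diff(pk$time), rep(1, length(pk$time) - 1L), tolerance = 1e-4)

  ct <- crossing_times(traj, "x", threshold = midpoint_threshold(p, f),
                       discard_before = 2)
  expect_equal(diff(ct$time), rep(1, length(ct$time) - 1L), tolerance = 1e-6)

  cv <- cv_from_intervals(pk)
  expect_lt(cv$cv, 1e-6)
})

test_that("quadratic interpolation locates peaks to sub-step accuracy", {
  dt <- 1e-3
  t <- seq(0, 5, by = dt)
  # deliberately sample off-grid so true peaks (at integers + 0.25) fall
  # between samples
  traj <- tibble::tibble(t = t, x = cos(2 * pi * (t - 0.25)))
  pk <- clockwave:::merge_peaks(
    cand_t = t, cand_v = traj$x, refractory = 0.5)
  # use the package path: refractory window peak detection
  m <- detect_peaks(structure(traj, class = c("clockwave_traj", class(traj))),
                    component = "x", discard_before = 0.5,
                    window = "refractory", refractory = 0.5)
  true_peaks <- (1:4) + 0.25
  found <- vapply(true_peaks, function(tp) m$time[which.min(abs(m$time - tp))], 0)
  expect_lt(max(abs(found - true_peaks)), dt)
})

test_that("multi-peaked waveforms yield exactly one marker per cycle", {
  p <- phase_params(epsilon = 0)
  f <- normalize_regfun(fourier_regfun(A = c(0.1, 0.6), B = c(0.55, 0.45)))
  traj <- simulate_phase_output(p, f, duration = 13)
  # the noiseless output has >1 local maximum per cycle
  x <- traj$x[traj$t > 2]
  i <- 2:(length(x) - 1L)
  n_max <- sum(x[i] >= x[i - 1L] & x[i] > x[i + 1L])
  expect_gt(n_max, 11)
  pk <- detect_peaks(traj, discard_before = 2)
  expect_true(nrow(pk) %in% c(10L, 11L))
  expect_equal(diff(pk$time), rep(1, nrow(pk) - 1L), tolerance = 1e-3)
})

test_that("refractory merging suppresses jitter-induced double crossings", {
  # sawtooth with white jitter: on the slow ramp the jitter produces a
  # cluster of upward crossings around the true one (well inside the
  # refractory window); the instant fall cannot produce spurious ups
  dt <- 1e-3
  t <- seq(0, 10, by = dt)
  set.seed(4)
  x <- 2 * (t %% 1) - 1 + 0.05 * stats::rnorm(length(t))
  traj <- tibble::new_tibble(list(t = t, x = x), class = "clockwave_traj")
  attr(traj, "params") <- list(tau = 1)
  n <- length(x)
  raw_up <- sum(x[-n] < 0 & x[-1] >= 0)
  expect_gt(raw_up, 9) # jitter creates extra raw crossings
  ct <- crossing_times(traj, "x", threshold = 0, discard_before = 1)
  expect_equal(nrow(ct), 9)
  expect_equal(diff(ct$time), rep(1, 8), tolerance = 0.05)
})

test_that("CV arithmetic follows the definition", {
  m <- tibble::tibble(time = cumsum(c(0, 1, 1, 1)))
  expect_equal(cv_from_intervals(m)$cv, 0)

  m2 <- tibble::tibble(time = cumsum(c(0, 0.9, 1.1)))
  est <- cv_from_intervals(m2)
  expect_equal(est$mean_period, 1.0)
  expect_equal(est$sd_period, stats::sd(c(0.9, 1.1)))
  expect_equal(est$cv, stats::sd(c(0.9, 1.1)), tolerance = 1e-12)
  expect_equal(est$se_cv, est$cv / sqrt(2 * 2))

  expect_error(cv_from_intervals(tibble::tibble(time = c(0, 1))),
               class = "clockwave_insufficient_data")
})

test_that("midpoint threshold equals the limit-cycle midpoint", {
  p <- phase_params()
  f <- fourier_regfun(0, 1)
  expect_equal(midpoint_threshold(p, f), 0.3, tolerance = 1e-8)
  expect_equal(midpoint_threshold(phase_params(beta = 0),
                                  fourier_regfun(1e-300, 0)), 0.3)
  # invariance under time shift of the drive (coefficient rotation)
  phi <- 1.1
  f2 <- fourier_regfun(A = sin(phi), B = cos(phi)) # sin(theta + phi)
  expect_equal(midpoint_threshold(p, f2), midpoint_threshold(p, f),
               tolerance = 1e-8)
})

test_that("period CV is invariant under affine output transformations", {
  # mechanism behind alpha/beta-independence: markers are peaks or
  # midpoint crossings, both equivariant under a*x + b with a > 0
  p <- phase_params()
  f <- normalize_regfun(fourier_regfun(A = c(0.2, 0.1), B = c(0.9, 0.3)))
  traj <- simulate_phase_output(p, f, duration = 120, seed = 8)
  cv0 <- cv_from_intervals(detect_peaks(traj, discard_before = 20))
  traj2 <- traj
  traj2$x <- 5.5 * traj$x + 2
  for (a in names(attributes(traj))) attr(traj2, a) <- attr(traj, a)
  cv1 <- cv_from_intervals(detect_peaks(traj2, discard_before = 20))
  expect_equal(cv1$cv, cv0$cv, tolerance = 1e-12)

  thr <- midpoint_threshold(p, f)
  c0 <- cv_from_intervals(crossing_times(traj, "x", thr, discard_before = 20))
  c1 <- cv_from_intervals(crossing_times(traj2, "x", 5.5 * thr + 2,
                                         discard_before = 20))
  expect_equal(c1$cv, c0$cv, tolerance = 1e-12)
})

test_that("data-frame pipeline and streaming engine agree", {
  p <- phase_params()
  fx <- make_fixtures()
  for (f in list(fourier_regfun(0, 1), fx$spiky)) {
    traj <- simulate_phase_output(p, f, duration = 120, seed = 99)
    r <- cv_from_intervals(detect_peaks(traj, discard_before = 20))
    s <- phase_period_cv(p, f, duration = 120, discard = 20, seed = 99)
    expect_equal(r$cv, s$cv, tolerance = 1e-10)
    expect_equal(r$n_intervals, s$n_intervals)
  }
})

test_that("peak-based and crossing-based CV estimate the same fluctuation", {
  p <- phase_params()
  fx <- make_fixtures()
  for (f in list(fx$broad, fx$spiky)) {
    pk <- phase_period_cv(p, f, duration = 2100, seed = 13, method = "peak")
    cr <- phase_period_cv(p, f, duration = 2100, seed = 14,
                          method = "crossing")
    se <- sqrt(pk$se_cv^2 + cr$se_cv^2)
    expect_lt(abs(pk$cv - cr$cv), 3 * se + 0.0015)
  }
})
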