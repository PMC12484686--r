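test_that("noiseless phase model is linear in time and settles to alpha/k", {
  p <- phase_params(epsilon = 0)
  f <- fourier_regfun(0, 1)
  traj <- simulate_phase_output(p, f, duration = 10, seed = 1)
  cm <- crossing_times(traj, "theta", threshold = pi, direction = "up",
                       discard_before = 1)
  expect_equal(diff(cm$time), rep(1, length(cm$time) - 1L), tolerance = 1e-9)

  late <- traj$x[traj$t > 5]
  expect_equal(mean(late), p$alpha / p$k, tolerance = 1e-3)

  # epsilon = 0 runs are seed-independent
  traj2 <- simulate_phase_output(p, f, duration = 10, seed = 999)
  expect_identical(traj$x, traj2$x)
  expect_identical(traj$theta, traj2$theta)
})

test_that("Euler-Maruyama with epsilon = 0 tracks a high-accuracy integrator", {
  skip_if_not_installed("deSolve")
  p <- phase_params(epsilon = 0)
  f <- normalize_regfun(fourier_regfun(A = c(0.3, 0.2), B = c(0.9, -0.1)))
  dt <- 1e-3
  traj <- simulate_phase_output(p, f, duration = 10, dt = dt, thin = 100L)
  rhs <- function(t, y, parms) {
    list(p$alpha + p$beta * eval_fourier(f, p$omega * t) - p$k * y)
  }
  sol <- deSolve::ode(c(x = 0), traj$t, rhs, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-10)
  expect_lt(max(abs(traj$x - sol[, "x"])), 20 * dt)

  # Goodwin loop: the clock equations carry the tau rescaling, so the
  # effective Euler step is tau*dt and absolute errors are larger; check
  # first-order convergence towards the reference solution instead
  gp <- ref_goodwin()
  g0 <- goodwin_params(epsilon = 0, tau = gp$tau)
  g <- polynomial_regulation(1, 1)
  grhs <- function(t, y, parms) {
    with(as.list(y), {
      hill <- 1 / (1 + max(w, 0)^gp$m)
      list(c(gp$tau * (hill - gp$ku * u),
             gp$tau * (u - gp$kv * v),
             gp$tau * (v - gp$kw * w),
             gp$alpha + gp$beta * w - gp$k * x))
    })
  }
  err <- vapply(c(1e-3, 2.5e-4), function(h) {
    tr <- simulate_goodwin_output(g0, g, duration = 5, dt = h,
                                  thin = as.integer(0.1 / h))
    sol <- deSolve::ode(c(u = 0, v = 0, w = 0, x = 0), tr$t, grhs, NULL,
                        method = "lsoda", rtol = 1e-11, atol = 1e-11)
    max(abs(tr$w - sol[, "w"]))
  }, 0)
  expect_lt(err[2], err[1])
  expect_gt(err[1] / err[2], 2.5) # ~4 for a first-order scheme
})

test_that("noise acts only through its specified channel", {
  p <- phase_params(epsilon = 0.1)
  f1 <- fourier_regfun(0, 1)
  f2 <- normalize_regfun(fourier_regfun(A = c(0.5, 0.3), B = c(0.6, 0.2)))
  t1 <- simulate_phase_output(p, f1, duration = 5, seed = 42)
  t2 <- simulate_phase_output(p, f2, duration = 5, seed = 42)
  # theta path depends only on the noise stream, not on f
  expect_identical(t1$theta, t2$theta)
  expect_false(identical(t1$x, t2$x))

  gp <- ref_goodwin()
  g1 <- polynomial_regulation(1, 1)
  g2 <- polynomial_regulation(c(4.558e-5, 1.555), c(10L, 0L))
  gt1 <- simulate_goodwin_output(gp, g1, duration = 5, seed = 42)
  gt2 <- simulate_goodwin_output(gp, g2, duration = 5, seed = 42)
  expect_identical(gt1$u, gt2$u)
  expect_identical(gt1$w, gt2$w)
  expect_false(identical(gt1$x, gt2$x))
})

test_that("phase increments satisfy the white-noise moment contract", {
  p <- phase_params(epsilon = 0.1, D = 3)
  f <- fourier_regfun(0, 1)
  dt <- 1e-3
  traj <- simulate_phase_output(p, f, duration = 50, dt = dt)
  thu <- clockwave:::unwrap_theta(traj$theta)
  inc <- diff(thu) - p$omega * dt
  n <- length(inc)
  sd_th <- p$epsilon * sqrt(p$D) * sqrt(dt)
  # mean within 3 sigma of zero; variance within 3 sigma of its chi-square sd
  expect_lt(abs(mean(inc)), 3 * sd_th / sqrt(n))
  expect_lt(abs(stats::var(inc) - sd_th^2), 3 * sd_th^2 * sqrt(2 / (n - 1)))
})

test_that("deterministic periods are measured correctly", {
  expect_equal(measure_deterministic_period("phase", phase_params()),
               1, tolerance = 1e-6)
  expect_equal(
    measure_deterministic_period("phase", phase_params(omega = pi)),
    2, tolerance = 1e-6)
  # Goodwin original period ~= 39.7 for the default rates
  gp <- ref_goodwin()
  expect_equal(measure_deterministic_period("goodwin", gp), 39.7,
               tolerance = 0.01)
  expect_error(goodwin_params(m = 2), class = "clockwave_non_oscillating")
})

test_that("limit-cycle solution has the right mean, amplitude and period", {
  p <- phase_params(epsilon = 0)
  fz <- fourier_regfun(1e-300, 0) # effectively zero drive
  expect_equal(limit_cycle_x(phase_params(beta = 0), fz, c(0, 0.3, 0.9)),
               rep(0.3, 3))

  f <- fourier_regfun(0, 1)
  tg <- seq(0, 1, by = 1e-4)
  xs <- limit_cycle_x(p, f, tg)
  expect_equal(mean(range(xs)), 0.3, tolerance = 1e-8)
  amp <- (max(xs) - min(xs)) / 2
  expect_equal(amp, 1 / sqrt(p$k^2 + p$omega^2), tolerance = 1e-7)

  # oracle: long epsilon = 0 simulation reaches the same cycle
  traj <- simulate_phase_output(p, f, duration = 6)
  late <- traj[traj$t > 5, ]
  expect_equal(max(late$x), max(xs) , tolerance = 1e-3)
  expect_equal(min(late$x), min(xs), tolerance = 1e-3)

  set.seed(3)
  g <- random_regfun(4)
  t0 <- stats::runif(5)
  expect_equal(limit_cycle_x(p, g, t0), limit_cycle_x(p, g, t0 + 1),
               tolerance = 1e-10)
})
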