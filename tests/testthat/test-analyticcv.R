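test_that("phase offsets follow the filter formula and its symmetries", {
  f <- fourier_regfun(0, 1)
  k <- 10
  omega <- 2 * pi
  off <- phase_offsets(f, k, omega, t_cp = 0)
  expect_equal(off$phi[1], atan(-omega / k), tolerance = 1e-12)

  set.seed(6)
  g <- random_regfun(4)
  o1 <- phase_offsets(g, k, omega, t_cp = 0.13)
  o2 <- phase_offsets(g, k, omega, t_cp = 0.13 + 0.21)
  expect_equal(o2$phi - o1$phi, (1:4) * omega * 0.21, tolerance = 1e-10)

  gs <- fourier_regfun(A = 3.7 * g$A, B = 3.7 * g$B)
  expect_equal(phase_offsets(gs, k, omega, 0.4)$phi,
               phase_offsets(g, k, omega, 0.4)$phi, tolerance = 1e-12)
})

test_that("checkpoint is the upward midpoint crossing of the limit cycle", {
  p <- phase_params()
  f <- fourier_regfun(0, 1)
  tcp <- checkpoint_time(p, f)
  expect_equal(limit_cycle_x(p, f, tcp), 0.3, tolerance = 1e-9)
  slope <- (limit_cycle_x(p, f, tcp + 1e-7) -
              limit_cycle_x(p, f, tcp - 1e-7)) / 2e-7
  expect_gt(slope, 0)
  # sine: crossing at the filter lag atan(omega/k)/omega
  expect_equal(tcp, atan(p$omega / p$k) / p$omega, tolerance = 1e-9)

  # time-shifted drive shifts the checkpoint by -phi/omega (mod tau)
  phi <- 0.7
  f2 <- fourier_regfun(A = sin(phi), B = cos(phi))
  tcp2 <- checkpoint_time(p, f2)
  expect_equal((tcp - tcp2) %% p$tau, phi / p$omega, tolerance = 1e-8)

  # beta sign flip moves the crossing half a period
  f3 <- fourier_regfun(0, -1)
  tcp3 <- checkpoint_time(p, f3)
  expect_equal(abs(tcp3 - tcp), p$tau / 2, tolerance = 1e-8)

  expect_error(checkpoint_time(p, fourier_regfun(1e-300, 0)),
               class = "clockwave_degenerate_function")
})

test_that("single-harmonic components match independent closed forms", {
  p <- phase_params(k = 10, omega = 2 * pi, epsilon = 0.1, D = 3)
  f <- fourier_regfun(0, 1)
  br <- cv_components(p, f)
  k <- p$k
  omega <- p$omega
  tau <- p$tau
  D <- p$D
  # for f = sin(theta) the checkpoint phase Phi_1(t_cp) = 0, so the double
  # sum collapses; derived by direct substitution
  ekt <- 1 - exp(-k * tau)
  expect_equal(br$R_theta_theta, D * tau^2 / (2 * pi * omega),
               tolerance = 1e-14)
  expect_equal(br$R_hh,
               D * ekt / omega^2 * (1 / (2 * k) + k / (2 * (k^2 + omega^2))),
               tolerance = 1e-9)
  expect_equal(br$R_theta_h,
               -D * ekt * k / (omega^2 * (k^2 + omega^2)),
               tolerance = 1e-9)
  expect_equal(br$cv, p$epsilon / tau *
                 sqrt(br$R_theta_theta + br$R_hh + 2 * br$R_theta_h),
               tolerance = 1e-14)
})

test_that("alpha/beta drop out and coefficient scale is irrelevant", {
  f <- normalize_regfun(fourier_regfun(A = c(0.4, 0.1), B = c(0.8, 0.3)))
  cvs <- vapply(c(1, 5, 23), function(a) {
    vapply(c(0.2, 1, 4), function(b) {
      analytic_cv(phase_params(alpha = a, beta = b), f)
    }, 0)
  }, numeric(3))
  expect_true(all(cvs == cvs[1, 1]))

  f_sc <- fourier_regfun(A = 17 * f$A, B = 17 * f$B)
  expect_equal(analytic_cv(phase_params(), f_sc),
               analytic_cv(phase_params(), f), tolerance = 1e-14)
})

test_that("zero-padding extra harmonics changes nothing", {
  set.seed(14)
  f <- random_regfun(3)
  fpad <- fourier_regfun(A = c(f$A, 0, 0), B = c(f$B, 0, 0))
  p <- phase_params()
  b1 <- cv_components(p, f)
  b2 <- cv_components(p, fpad)
  expect_equal(b2$cv, b1$cv, tolerance = 1e-14)
  expect_equal(b2$R_hh, b1$R_hh, tolerance = 1e-14)
  expect_equal(b2$R_theta_h, b1$R_theta_h, tolerance = 1e-14)
})

test_that("clock CV follows epsilon * sqrt(D / (2 pi omega))", {
  expect_equal(clock_cv(0.1, 3, 2 * pi), 0.1 * sqrt(3 / (4 * pi^2)),
               tolerance = 1e-15)
  expect_equal(clock_cv(0.1, 0, 2 * pi), 0)
  expect_equal(clock_cv(0.2, 4 * 1.3, 5), 2 * clock_cv(0.2, 1.3, 5),
               tolerance = 1e-15)
})

test_that("radicand stays positive and fast batch path matches the R path", {
  set.seed(31)
  p <- phase_params()
  coefs <- matrix(stats::runif(20 * 6, -1, 1), 20, 6)
  coefs[abs(coefs[, 1]) + abs(coefs[, 2]) < 0.05, 1] <- 0.5
  batch <- clockwave:::cpp_analytic_cv_batch(coefs, p$k, p$omega,
                                             p$epsilon, p$D)
  for (r in seq_len(nrow(coefs))) {
    f <- regfun_from_coefs(coefs[r, ])
    br <- cv_components(p, f)
    expect_gt(br$R_theta_theta + br$R_hh + 2 * br$R_theta_h, 0)
    expect_equal(br$cv, unname(batch[r, "cv"]), tolerance = 1e-10)
    expect_equal(br$t_cp, unname(batch[r, "t_cp"]), tolerance = 1e-8)
  }
})

test_that("closed form agrees with small-noise simulation", {
  f <- normalize_regfun(fourier_regfun(A = c(0.2, 0.15), B = c(0.9, 0.1)))
  p <- phase_params(epsilon = 0.02, alpha = 3, beta = 1)
  sim <- phase_period_cv(p, f, duration = 4200, discard = 100, seed = 23,
                         method = "crossing")
  ana <- analytic_cv(p, f)
  expect_lt(abs(sim$cv - ana), 3 * sim$se_cv)
})
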