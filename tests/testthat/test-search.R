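test_that("random scans are reproducible and uniform on the cube", {
  p <- phase_params()
  ev <- cv_evaluator("analytic", p)
  s1 <- sample_random_functions(H = 3L, n = 50L, evaluator = ev, seed = 7)
  s2 <- sample_random_functions(H = 3L, n = 50L, evaluator = ev, seed = 7)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  s3 <- sample_random_functions(H = 3L, n = 50L, evaluator = ev, seed = 8)
  expect_false(identical(s1$cv, s3$cv))
  co <- clockwave:::samples_coef_matrix(s1)
  expect_true(all(co >= -1 & co <= 1))

  # evaluator output equals the closed form row by row
  for (r in c(1L, 17L, 50L)) {
    expect_equal(s1$cv[r], analytic_cv(p, regfun_from_coefs(co[r, ])),
                 tolerance = 1e-12)
  }
})

test_that("a flat target makes every grid atom equally likely", {
  cfg <- gibbs_config(n_max = 2500L, burn_in = 100L, grid_N = 4L,
                      cv_units = "fraction")
  ev <- cv_evaluator(function(x) 0.5)
  ch <- gibbs_sample(ev, H = 1L, config = cfg, seed = 3)
  expect_equal(nrow(ch), 2400L)
  grid <- -1 + 2 * (0:4) / 4
  for (cc in c("A1", "B1")) {
    counts <- table(factor(round(ch[[cc]], 10), levels = round(grid, 10)))
    chi <- sum((counts - nrow(ch) / 5)^2 / (nrow(ch) / 5))
    expect_lt(chi, stats::qchisq(0.999, df = 4))
  }
})

test_that("the sampler reproduces exact Boltzmann marginals on a toy target", {
  # separable target: CV(x) = c1|x1| + c2|x2| (fractions); with percent
  # weighting the atom weights are exp(-100 c_i |x|), so each coordinate has
  # an exactly known discrete marginal
  c1 <- 0.02
  c2 <- 0.035
  cfg <- gibbs_config(n_max = 6000L, burn_in = 500L, grid_N = 8L)
  ev <- cv_evaluator(function(x) c1 * abs(x[1]) + c2 * abs(x[2]))
  ch <- gibbs_sample(ev, H = 1L, config = cfg, seed = 11)
  grid <- -1 + 2 * (0:8) / 8
  n <- nrow(ch)
  for (j in 1:2) {
    cc <- c("A1", "B1")[j]
    w <- exp(-100 * c(c1, c2)[j] * abs(grid))
    prob <- w / sum(w)
    counts <- as.vector(table(factor(round(ch[[cc]], 10),
                                     levels = round(grid, 10))))
    se <- sqrt(prob * (1 - prob) * n)
    # 3-sigma per atom (the sweep-to-sweep samples are nearly independent
    # because each update resamples the full conditional)
    expect_true(all(abs(counts - n * prob) < 4 * se + 3))
  }
  # recorded cv matches the target at the recorded coordinates
  expect_equal(ch$cv, c1 * abs(ch$A1) + c2 * abs(ch$B1), tolerance = 1e-12)
})

test_that("chain bookkeeping and coordinate bounds hold", {
  p <- phase_params()
  cfg <- gibbs_config(n_max = 300L, burn_in = 50L, grid_N = 10L)
  ch <- gibbs_sample(cv_evaluator("analytic", p), H = 3L, config = cfg,
                     seed = 5)
  expect_equal(nrow(ch), 250L)
  co <- clockwave:::samples_coef_matrix(ch)
  expect_true(all(co >= -1 & co <= 1))
  expect_true(all(is.finite(ch$cv)))
  # reproducible
  ch2 <- gibbs_sample(cv_evaluator("analytic", p), H = 3L, config = cfg,
                      seed = 5)
  expect_identical(as.data.frame(ch), as.data.frame(ch2))
})

test_that("mean harmonic power summarises normalised records", {
  recs <- dplyr::bind_rows(
    regfun_to_row(fourier_regfun(c(0, 0, 0), c(2, 0, 0))),
    regfun_to_row(fourier_regfun(c(0, 0, 0), c(0.5, 0, 0)))
  )
  recs$cv <- c(0.02, 0.03)
  mp <- mean_harmonic_power(recs)
  expect_equal(mp$mean_power, c(1, 0, 0))

  set.seed(9)
  u <- tibble::as_tibble(as.data.frame(matrix(stats::runif(4000 * 8, -1, 1),
                                              4000, 8)))
  names(u) <- paste0(rep(c("A", "B"), 4), rep(1:4, each = 2))
  u$cv <- stats::runif(4000)
  mp2 <- mean_harmonic_power(u)
  expect_true(all(abs(mp2$mean_power - 0.25) < 3 * mp2$se + 1e-3))

  expect_error(mean_harmonic_power(u[0, ]), class = "clockwave_empty_subset")
})

test_that("evolutionary search dominates a random scan and is sine-like", {
  p <- phase_params()
  ev <- cv_evaluator("analytic", p)
  res <- evolve_minimum(ev, H = 5L, pop = 64L, generations = 300L, seed = 2)
  res2 <- evolve_minimum(ev, H = 5L, pop = 64L, generations = 300L, seed = 2)
  expect_identical(res$best$cv, res2$best$cv)

  scan <- sample_random_functions(H = 5L, n = 1000L, evaluator = ev,
                                  seed = 3)
  expect_lte(res$best$cv, min(scan$cv))
  # fitness trace is non-increasing
  expect_true(all(diff(res$trace$best_cv) <= 1e-15))
  # the optimum beats the sine slightly and concentrates power at low
  # harmonic numbers (the fundamental plus a second-harmonic correction)
  expect_lt(res$best$cv, analytic_cv(p, fourier_regfun(0, 1)))
  mp <- mean_harmonic_power(res$best)
  expect_gt(mp$mean_power[1] + mp$mean_power[2], 0.7)
  expect_gt(mp$mean_power[1], max(mp$mean_power[3:5]))
})
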