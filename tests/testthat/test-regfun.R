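test_that("Fourier evaluation matches identities and the brute-force oracle", {
  f <- fourier_regfun(A = 0, B = 1)
  expect_equal(eval_fourier(f, pi / 2), 1.0, tolerance = 1e-12)

  f2 <- fourier_regfun(A = 0.6, B = 0.8)
  expect_equal(eval_fourier(f2, 0), 0.6, tolerance = 1e-12)

  set.seed(11)
  for (H in c(1L, 3L, 8L)) {
    f <- random_regfun(H)
    theta <- stats::runif(25, -10, 10)
    expect_equal(eval_fourier(f, theta), brute_fourier(f$A, f$B, theta),
                 tolerance = 1e-12)
    expect_equal(eval_fourier(f, theta), eval_fourier(f, theta + 2 * pi),
                 tolerance = 1e-12)
  }
})

test_that("normalisation scales to unit power, idempotently and scale-invariantly", {
  f <- normalize_regfun(fourier_regfun(A = 3, B = 4))
  expect_equal(f$A, 0.6, tolerance = 1e-12)
  expect_equal(f$B, 0.8, tolerance = 1e-12)
  expect_true(f$normalized)

  f4 <- normalize_regfun(fourier_regfun(A = c(1, 1), B = c(1, 1)))
  expect_equal(c(f4$A, f4$B), rep(0.5, 4), tolerance = 1e-12)

  set.seed(21)
  g <- random_regfun(4)
  n1 <- normalize_regfun(g)
  expect_equal(normalize_regfun(n1), n1, tolerance = 1e-12)
  scaled <- fourier_regfun(A = 2.7 * g$A, B = 2.7 * g$B)
  n2 <- normalize_regfun(scaled)
  expect_equal(n1$A, n2$A, tolerance = 1e-12)
  expect_equal(n1$B, n2$B, tolerance = 1e-12)
  expect_equal(sum(harmonic_power(n1)$power), 1, tolerance = 1e-12)

  expect_error(fourier_regfun(A = 0, B = 0),
               class = "clockwave_invalid_function")
})

test_that("harmonic power reports r_i^2 per harmonic", {
  f <- fourier_regfun(A = c(0, 0, 0), B = c(1, 0, 0))
  expect_equal(harmonic_power(f)$power, c(1, 0, 0))
  f2 <- fourier_regfun(A = c(1e-9, 0.6), B = c(0, 0.8))
  expect_equal(harmonic_power(f2)$power[2], 1.0, tolerance = 1e-12)
})

test_that("polynomial regulation evaluates the printed fixtures", {
  expect_equal(eval_polynomial(polynomial_regulation(1, 1), 2.5), 2.5)
  sharp10 <- polynomial_regulation(c(4.558e-5, 1.555), c(10L, 0L))
  expect_equal(eval_polynomial(sharp10, 0), 1.555)
  sharp15 <- polynomial_regulation(c(2.783e-7, 1.559), c(15L, 0L))
  expect_equal(eval_polynomial(sharp15, 1), 1.559 + 2.783e-7,
               tolerance = 1e-15)
  expect_error(polynomial_regulation(2, 0),
               class = "clockwave_invalid_function")
})

test_that("rate positivity is certified on the grid and by the bound", {
  set.seed(5)
  for (rep in 1:5) {
    f <- random_regfun(5, normalized = TRUE)
    res <- check_rate_positivity(3, 1, f)
    expect_true(res$ok) # |f| <= sqrt(5) < 3 for unit power
  }
  res0 <- check_rate_positivity(0, 1, fourier_regfun(0, 1))
  expect_false(res0$ok)
  expect_equal(res0$min_rate, -1, tolerance = 1e-6)
  resb <- check_rate_positivity(1, 0, random_regfun(3))
  expect_true(resb$ok)
  expect_equal(resb$min_rate, 1)
})

test_that("flat-record and JSON serialisation round-trip", {
  set.seed(9)
  f <- random_regfun(3)
  row <- regfun_to_row(f)
  expect_named(row, c("H", "A1", "B1", "A2", "B2", "A3", "B3"))
  f2 <- regfun_from_row(row)
  expect_equal(f2$A, f$A)
  expect_equal(f2$B, f$B)

  g <- polynomial_regulation(c(4.558e-5, 1.555), c(10L, 0L))
  g2 <- polynomial_from_json(polynomial_to_json(g))
  expect_equal(g2$coef, g$coef)
  expect_equal(g2$power, g$power)

  expect_equal(regfun_coefs(regfun_from_coefs(c(1, 2, 3, 4))), c(1, 2, 3, 4))
})
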