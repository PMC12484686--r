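test_that("fixtures have the documented values and satisfy positivity", {
  fx <- make_fixtures()
  expect_equal(harmonic_power(fx$sine)$power, 1)
  expect_true(fx$sine$normalized)
  expect_equal(eval_polynomial(fx$sharp10, 0), 1.555)
  expect_equal(eval_polynomial(fx$sharp15, 0), 1.559)
  expect_equal(eval_polynomial(fx$linear, 3.2), 3.2)
  for (nm in c("sine", "broad", "spiky")) {
    expect_true(check_rate_positivity(3, 1, fx[[nm]])$ok)
    expect_equal(sum(harmonic_power(fx[[nm]])$power), 1, tolerance = 1e-12)
  }
})

test_that("experiments write reproducible result bundles", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  r1 <- run_experiment("agreement", out_dir = out1, seed = 4, scale = 0.02)
  r2 <- run_experiment("agreement", out_dir = out2, seed = 4, scale = 0.02)
  expect_identical(r1, r2)
  expect_true(file.exists(file.path(out1, "results.csv")))
  expect_true(file.exists(file.path(out1, "manifest.json")))
  expect_true(file.exists(file.path(out1, "run.log")))
  expect_identical(readLines(file.path(out1, "results.csv")),
                   readLines(file.path(out2, "results.csv")))
  man <- jsonlite::fromJSON(file.path(out1, "manifest.json"))
  expect_equal(man$seed, 4)
  expect_equal(man$scale, 0.02)
  expect_equal(man$experiment, "agreement")
  expect_named(r1, c("regulation", "epsilon", "cv_numeric", "cv_analytic",
                     "n_intervals"))
})

test_that("unknown experiments and bad scales are rejected", {
  expect_error(run_experiment("nonsense"))
  expect_error(run_experiment("agreement", scale = 0))
})

test_that("parameter sweep experiment returns the full grid", {
  r <- run_experiment("param_sweeps", seed = 2, scale = 0.02)
  expect_setequal(unique(r$sweep), c("alpha", "beta"))
  expect_equal(nrow(r), 3L * (5L + 4L))
  expect_true(all(r$cv > 0))
})
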