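test_that("quadratic fits interpolate three points and handle edge shapes", {
  co <- polyfit_quadratic(c(0, 12, 24), c(7.7275, 4.7275, 3.5707))
  expect_equal(unname(co[["c"]]), 7.7275, tolerance = 1e-10)
  expect_equal(unname(polyfit_quadratic(0:5, rep(3.2, 6))),
               c(0, 0, 3.2), tolerance = 1e-10)
  xs <- seq(-4, 4, length.out = 9)
  expect_equal(unname(polyfit_quadratic(xs, xs^2)), c(1, 0, 0),
               tolerance = 1e-10)
  expect_error(polyfit_quadratic(c(1, 1, 2), c(0, 0, 1)), "3 distinct")
})

test_that("OLS recovers the generating coefficients from noise-free cohorts", {
  for (mode in c("pregnant", "postpartum")) {
    spec <- cohort_spec(mode, n_subjects = 60, noise_sd_cm = 0, seed = 11)
    rec <- generate_cohort(spec)
    fit <- fit_measurement_regression(rec, mode)
    expect_lt(max(abs(fit$table - regression_coefficients(mode)$table)), 1e-6)
  }
})

test_that("rank-deficient or undersized designs are rejected", {
  spec <- cohort_spec("pregnant", n_subjects = 60, noise_sd_cm = 0, seed = 3)
  rec <- generate_cohort(spec)
  expect_error(fit_measurement_regression(rec[1:3, ], "pregnant"), "singular")
  rec$height_cm <- 160  # constant column collinear with the intercept
  expect_error(fit_measurement_regression(rec, "pregnant"), "singular")
})

test_that("noisy recovery at the published cohort size is unbiased", {
  # chest weight-gain coefficient across seeded replicates, noise SD 1 cm
  ests <- vapply(1:25, function(s) {
    spec <- cohort_spec("pregnant", n_subjects = 98, noise_sd_cm = 1,
                        visit_retention = "published", seed = 1000 + s)
    fit_measurement_regression(generate_cohort(spec), "pregnant")$table["chest", "weight_gain_kg"]
  }, 0)
  expect_lt(abs(mean(ests) - 0.457), 0.05)
  expect_gt(mean(abs(ests - 0.457) < 0.1), 0.9)
})

test_that("agreement statistics reproduce the published comparison numbers", {
  # chest row of the pregnant model-vs-cross-section comparison:
  # means 94.51 / 95.30, SD 10.49, n = 30
  s <- agreement_from_moments(94.51, 10.49, 95.30, 10.86, 30, "first")
  expect_equal(round(s$relative_error_pct, 3), 0.836)
  expect_equal(round(s$ci_lower[1], 2), 90.76)
  expect_equal(round(s$ci_upper[1], 2), 98.26)
  expect_equal(round(s$ci_lower[2], 2), 91.41)
})

test_that("agreement on raw pairs adds the correlation and guards degeneracy", {
  x <- c(94, 95.2, 96.4, 93.8, 97)
  s <- agreement_stats(x, x, "first")
  expect_equal(s$relative_error_pct, 0)
  expect_equal(s$correlation, 1)
  expect_equal(s$ci_lower[1], mean(x) - 1.96 * sd(x) / sqrt(5))
  expect_error(agreement_stats(rep(2, 5), x), "zero variance")
  expect_error(agreement_stats(1:3, 1:4), "paired")
})

test_that("the relative-error reference series is switchable", {
  s1 <- agreement_from_moments(100, 5, 90, 5, 10, "first")
  s2 <- agreement_from_moments(100, 5, 90, 5, 10, "second")
  expect_equal(s1$relative_error_pct, 10)
  expect_equal(s2$relative_error_pct, 10 / 90 * 100)
})

test_that("calibration grids validate their density", {
  expect_error(calibration_grid("pregnant", bmi = c(20, 25)), ">= 3 distinct")
  g <- calibration_grid("postpartum")
  expect_equal(g$weeks, c(0, 8, 16, 24))
})
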