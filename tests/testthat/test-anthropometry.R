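test_that("bmi computes kg/m^2 and rejects non-positive inputs", {
  expect_equal(bmi(100, 100), 100)
  expect_equal(bmi(60, 165), 60 / 1.65^2)
  expect_error(bmi(0, 165), "positive")
  expect_error(bmi(60, -1), "positive")
})

test_that("pregnant regression reproduces the published coefficient rows", {
  co <- regression_coefficients("pregnant")
  # intercept alone: all covariates zero is outside the profile domain, so
  # evaluate the linear form directly
  expect_equal(unname(co$table["chest", "intercept"]), 69.896)
  p <- pregnancy_profile(60, 160, gestational_week = 24, age_years = 30,
                         gravida = 1, weight_gain_kg = 8)
  m <- predict_pregnant_measurements(p)
  expect_equal(unname(m[["chest_cm"]]), 94.882, tolerance = 1e-10)
  # one extra kilogram of gestational gain moves chest by its F coefficient
  p2 <- pregnancy_profile(60, 160, gestational_week = 24, age_years = 30,
                          gravida = 1, weight_gain_kg = 9)
  m2 <- predict_pregnant_measurements(p2)
  expect_equal(unname(m2[["chest_cm"]] - m[["chest_cm"]]), 0.457,
               tolerance = 1e-10)
  # inseam is the static baseline at pre-pregnancy weight, height passes through
  expect_equal(unname(m[["inseam_cm"]]),
               unname(baseline_measurements(60, 160)[["inseam_cm"]]))
  expect_equal(unname(m[["height_cm"]]), 160)
})

test_that("postpartum regression reproduces the published coefficient rows", {
  co <- regression_coefficients("postpartum")
  expect_equal(unname(co$table["chest", "intercept"]), 53.038)
  p <- postpartum_profile(60, 160, postpartum_week = 12, age_years = 30,
                          gravida = 1, baby_weight_kg = 3,
                          postpartum_weight_kg = 65)
  m <- predict_postpartum_measurements(p)
  expect_equal(unname(m[["chest_cm"]]), 91.467, tolerance = 1e-10)
  p2 <- postpartum_profile(60, 160, postpartum_week = 12, age_years = 30,
                           gravida = 1, baby_weight_kg = 3,
                           postpartum_weight_kg = 66)
  m2 <- predict_postpartum_measurements(p2)
  expect_equal(unname(m2[["hip_cm"]] - m[["hip_cm"]]), 0.780, tolerance = 1e-10)
})

test_that("baseline linear forms match the published equations", {
  b <- baseline_measurements(60, 165)
  expect_equal(unname(b[["chest_cm"]]),
               0.872260 * 60 - 0.437949 * 165 + 110.131573)
  expect_equal(unname(b[["chest_cm"]]), 90.2056, tolerance = 1e-4)
  # consistent with the thin avatar's stated default leg length of ~73 cm
  expect_equal(unname(b[["inseam_cm"]]), 72.598, tolerance = 1e-3)
  # analytic anchor: the chest intercept, checks disabled
  expect_equal(unname(baseline_measurements(0, 0, .validate = FALSE)[["chest_cm"]]),
               110.131573)
  expect_error(baseline_measurements(0, 0), "positive")
})

test_that("profiles validate their domains and apply defaults only when absent", {
  expect_error(pregnancy_profile(60, 160, gestational_week = 50), "\\[0, 42\\]")
  expect_error(pregnancy_profile(60, 160, gestational_week = 24, gravida = 0),
               "gravida")
  expect_warning(postpartum_profile(60, 160, postpartum_week = 30), "clamp")
  p <- pregnancy_profile(60, 160, gestational_week = 24)
  expect_equal(p$age_years, 30)
  expect_equal(p$gravida, 1)
  p2 <- pregnancy_profile(60, 160, gestational_week = 24, age_years = 41)
  expect_equal(p2$age_years, 41)
  pp <- postpartum_profile(60, 160, postpartum_week = 4)
  expect_equal(pp$baby_weight_kg, 3)
})

test_that("mode mismatch and implausible extrapolation are rejected", {
  p <- pregnancy_profile(60, 160, gestational_week = 24, weight_gain_kg = 8)
  expect_error(predict_pregnant_measurements(p, regression_coefficients("postpartum")),
               "mode")
  # extreme extrapolation driving a girth negative errors instead of clamping
  bad <- pregnancy_profile(1, 400, gestational_week = 0, weight_gain_kg = -5,
                           age_years = 1)
  expect_error(predict_pregnant_measurements(bad), "non-positive girth")
})

test_that("prediction is linear: mean of predictions equals prediction at the mean", {
  set.seed(42)
  n <- 50
  profs <- lapply(seq_len(n), function(i)
    pregnancy_profile(runif(1, 45, 90), runif(1, 150, 175),
                      gestational_week = runif(1, 12, 36),
                      age_years = runif(1, 20, 40),
                      gravida = sample(1:2, 1),
                      weight_gain_kg = runif(1, 0, 15)))
  preds <- vapply(profs, function(p)
    predict_pregnant_measurements(p)[["waist_cm"]], 0)
  mean_prof <- pregnancy_profile(
    mean(vapply(profs, `[[`, 0, "pre_pregnancy_weight_kg")),
    mean(vapply(profs, `[[`, 0, "height_cm")),
    gestational_week = mean(vapply(profs, `[[`, 0, "gestational_week")),
    age_years = mean(vapply(profs, `[[`, 0, "age_years")),
    gravida = mean(vapply(profs, `[[`, 0, "gravida")),
    weight_gain_kg = mean(vapply(profs, `[[`, 0, "weight_gain_kg")))
  expect_equal(mean(preds),
               predict_pregnant_measurements(mean_prof)[["waist_cm"]],
               tolerance = 1e-10)
})

test_that("coefficient tables round-trip through CSV bit-identically", {
  for (mode in c("pregnant", "postpartum")) {
    co <- regression_coefficients(mode)
    path <- withr::local_tempfile(fileext = ".csv")
    write_coefficients_csv(co, path)
    co2 <- read_coefficients_csv(path, mode)
    expect_identical(co$table, co2$table)
  }
})
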