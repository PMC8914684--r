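test_that("BMI classification is total with half-open boundaries", {
  expect_equal(classify_bmi(18.4), "underweight")
  expect_equal(classify_bmi(18.5), "normal")
  expect_equal(classify_bmi(24.95), "normal")
  expect_equal(classify_bmi(25.0), "overweight")
  expect_equal(classify_bmi(30.0), "obese")
  expect_equal(classify_bmi(55), "obese")
  expect_error(classify_bmi(0), "positive")
  # total and single-valued over a fine grid
  for (b in seq(10, 45, by = 0.5)) expect_length(classify_bmi(b), 1L)
})

test_that("IOM average gains are the midpoints of the recommended ranges", {
  expect_equal(iom_average_gwg("underweight"), 15.455)
  expect_equal(iom_average_gwg("normal"), 13.635)
  expect_equal(iom_average_gwg("overweight"), 9.09)
  expect_equal(iom_average_gwg("obese"), 7.045)
  pol <- gwg_policy()
  expect_equal(vapply(pol$category, iom_average_gwg, 0, USE.NAMES = FALSE),
               (pol$total_lo_kg + pol$total_hi_kg) / 2)
})

test_that("gestational weight gain accrues to the published anchors", {
  for (ct in gwg_policy()$category) {
    expect_equal(predict_weight_gain(ct, 0), 0)
    expect_equal(predict_weight_gain(ct, 40), iom_average_gwg(ct),
                 tolerance = 1e-12)
  }
  # trimester 2-3 rate: first-trimester remainder plus 12 weeks at 0.45/wk
  expect_equal(predict_weight_gain("underweight", 24), 2.855 + 0.45 * 12)
  expect_equal(predict_weight_gain("underweight", 24), 8.255)
  # non-decreasing in week
  for (ct in gwg_policy()$category) {
    g <- vapply(seq(0, 40, by = 1), function(w) predict_weight_gain(ct, w), 0)
    expect_true(all(diff(g) >= -1e-12))
  }
  expect_warning(predict_weight_gain("normal", 41), "clamp")
})

test_that("rule of three reproduces the published six-month retentions", {
  src <- retention_sources()
  u <- src[src$category == "underweight", ]
  expect_equal(round(retention_rule_of_three(u$huang_retention_6mo_kg,
                                             u$iom_avg_gwg_kg, u$huang_gwg_kg), 3),
               3.573)
  o <- src[src$category == "obese", ]
  expect_equal(round(retention_rule_of_three(o$huang_retention_6mo_kg,
                                             o$iom_avg_gwg_kg, o$huang_gwg_kg), 3),
               -0.183)
  # identity when the two gains coincide
  expect_equal(retention_rule_of_three(4.2, 11, 11), 4.2)
  expect_error(retention_rule_of_three(1, 1, 0), "non-zero")
})

test_that("retention curves are anchored at half the IOM average and convex", {
  expect_equal(predict_retention("underweight", 0), 7.7275)
  expect_equal(predict_retention("normal", 0), 6.8175)
  expect_equal(predict_retention("overweight", 0), 4.545)
  expect_equal(predict_retention("obese", 0), 3.5225)
  for (ct in retention_curves()$category)
    expect_equal(predict_retention(ct, 0), iom_average_gwg(ct) / 2,
                 tolerance = 1e-12)
  expect_equal(predict_retention("obese", 24), 0.0057 * 576 - 0.2915 * 24 + 3.5225)
  expect_equal(predict_retention("obese", 24), -0.1903, tolerance = 1e-12)
  expect_true(all(retention_curves()$a > 0))
  expect_warning(predict_retention("normal", 30), "clamp")
})

test_that("postpartum weight is pre-pregnancy weight plus retention", {
  expect_equal(predict_postpartum_weight(60, "normal", 0), 66.8175)
  expect_equal(predict_postpartum_weight(60, "obese", 24), 59.8097)
  for (wk in c(0, 6, 13, 24))
    expect_equal(predict_postpartum_weight(72, "overweight", wk) - 72,
                 predict_retention("overweight", wk))
})
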