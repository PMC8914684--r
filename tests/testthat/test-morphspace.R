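test_that("base weights are the published affine rescalings", {
  m0 <- c(chest_cm = 57, waist_cm = 40, hip_cm = 68, height_cm = 165,
          inseam_cm = 78)
  k <- base_weights(m0)
  expect_equal(unname(k[c("k00", "k01", "k02", "k03", "k04", "k05")]),
               c(0, 0, 0, 0, 0, 0))
  expect_equal(unname(base_weights(replace(m0, 1, 200))[["k01"]]), 1)
  expect_equal(unname(base_weights(replace(m0, 4, 199))[["k04"]]), 1.36)
  # inseam axis: the offset anchor 78 over the 48..120 range
  expect_equal(unname(base_weights(replace(m0, 5, 120))[["k05"]]), 42 / 72)
})

test_that("a zero tensor yields zero corrections and K equals base weights", {
  zero <- alp_calibration("pregnant",
                          matrix(0, 18, 3, dimnames = dimnames(alp_calibration("pregnant")$tensor)))
  expect_equal(unname(alp_corrections(zero, 22, 24)), rep(0, 6))
  meas <- c(baseline_measurements(60, 165), height_cm = 165)
  w <- morph_weights(meas, 22, 24, zero, "pregnant")
  expect_equal(as.numeric(w), unname(base_weights(meas)))
})

test_that("tensor rows evaluate as week quadratics (published Alp01 value)", {
  tens <- matrix(0, 18, 3, dimnames = dimnames(alp_calibration("pregnant")$tensor))
  tens["Alp01", ] <- c(A = -6.956e-3, B = 4.582e-4, C = -8.577e-6)
  cal <- alp_calibration("pregnant", tens)
  # with only the Alp01 row, alp0 = Alp01(week) * bmi^2; at bmi 1, week 24
  expect_equal(unname(alp_corrections(cal, 1, 24)[["alp0"]]),
               -8.577e-6 * 576 + 4.582e-4 * 24 - 6.956e-3, tolerance = 1e-12)
  expect_equal(unname(alp_corrections(cal, 1, 24)[["alp0"]]), -8.995e-4,
               tolerance = 1e-4)
})

test_that("early gestation scales the belly correction linearly to zero", {
  cal <- alp_calibration("pregnant")
  a12 <- alp_corrections(cal, 22, 12)
  a6 <- alp_corrections(cal, 22, 6)
  a0 <- alp_corrections(cal, 22, 0)
  expect_equal(a6[["alp0"]], a12[["alp0"]] / 2, tolerance = 1e-12)
  expect_equal(a0[["alp0"]], 0)
  # the non-belly corrections are held at their week-12 values
  expect_equal(a6[paste0("alp", 1:5)], a12[paste0("alp", 1:5)])
})

test_that("postpartum corrections and weights carry no belly component", {
  cal <- alp_calibration("postpartum")
  expect_equal(alp_corrections(cal, 25, 8)[["alp0"]], 0)
  meas <- c(baseline_measurements(60, 165), height_cm = 165)
  w <- morph_weights(meas, 25, 8, cal, "postpartum")
  expect_equal(w[["k0"]], 0)
  expect_error(new_morph_weights(c(k0 = 0.2), "postpartum"), "belly")
})

test_that("morph weights vary continuously in week", {
  cal <- alp_calibration("pregnant")
  meas <- c(baseline_measurements(60, 165), height_cm = 165)
  for (wk in c(6, 11.999, 12.001, 25, 39)) {
    w1 <- unclass(morph_weights(meas, 22, wk, cal, "pregnant"))
    w2 <- unclass(morph_weights(meas, 22, wk + 1e-6, cal, "pregnant"))
    expect_lt(max(abs(w1 - w2)), 1e-5)
  }
})

test_that("blending reproduces pure avatars and is affine in the weights", {
  av <- test_avatars()
  m0 <- blend(av, new_morph_weights(numeric(0), "pregnant"))
  expect_equal(m0$vertices, av$thin$vertices, tolerance = 1e-14)
  m1 <- blend(av, suppressWarnings(new_morph_weights(c(k1 = 1), "pregnant")))
  expect_equal(m1$vertices, av$big_breast$vertices, tolerance = 1e-14)
  mx <- blend(av, suppressWarnings(new_morph_weights(c(k0 = 1), "pregnant")))
  expect_equal(mx$vertices, av$pregnant_thin$vertices, tolerance = 1e-14)
  # affinity per vertex: blend(aK) - blend(0) = a * (blend(K) - blend(0))
  k <- c(k0 = 0.2, k1 = 0.15, k2 = 0.3, k3 = 0.1, k4 = -0.05, k5 = 0.08)
  for (a in c(0.25, 0.5, 2)) {
    d1 <- blend(av, suppressWarnings(new_morph_weights(a * k, "pregnant")))$vertices -
      m0$vertices
    d2 <- blend(av, suppressWarnings(new_morph_weights(k, "pregnant")))$vertices -
      m0$vertices
    expect_equal(d1, a * d2, tolerance = 1e-10)
  }
})

test_that("week-0 pregnant synthesis carries no belly weight", {
  w <- morph_weights(c(baseline_measurements(60, 165), height_cm = 165),
                     22, 0, alp_calibration("pregnant"), "pregnant")
  expect_equal(w[["k0"]], unname(base_weights(c(baseline_measurements(60, 165),
                                                height_cm = 165))[["k00"]]))
  expect_equal(w[["k0"]], 0)
})

test_that("out-of-band weights warn but are never clamped", {
  expect_warning(w <- new_morph_weights(c(k1 = 1.8), "pregnant"), "sanity band")
  expect_equal(w[["k1"]], 1.8)
})

test_that("alp tensors round-trip through JSON", {
  for (mode in c("pregnant", "postpartum")) {
    cal <- alp_calibration(mode)
    path <- withr::local_tempfile(fileext = ".json")
    write_alp_json(cal, path)
    back <- read_alp_json(path)
    expect_equal(back$tensor, cal$tensor)
    expect_equal(back$mode, mode)
  }
})

test_that("blending rejects topology mismatches", {
  av <- test_avatars()
  broken <- av
  broken$tall <- mesh3(av$tall$vertices[-1, , drop = FALSE],
                       matrix(1:3, 1))
  expect_error(blend(broken, new_morph_weights(numeric(0), "pregnant")),
               "topology")
})
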