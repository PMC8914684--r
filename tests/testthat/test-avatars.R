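test_that("generation is deterministic and topology-identical", {
  a1 <- generate_synthetic_avatars(n_theta = 20, ring_step_cm = 5, verify = FALSE)
  a2 <- generate_synthetic_avatars(n_theta = 20, ring_step_cm = 5, verify = FALSE)
  for (role in names(a1)) {
    expect_identical(a1[[role]]$vertices, a2[[role]]$vertices)
    expect_identical(a1[[role]]$faces, a1$thin$faces)
  }
  nv <- vapply(a1, function(m) nrow(m$vertices), 1L)
  expect_length(unique(nv), 1L)
})

test_that("anchor dimensions hit their targets within 2%", {
  av <- test_avatars()
  expect_gt(measure_all(av$thin)[["waist_cm"]], 39.2)
  expect_lt(measure_all(av$thin)[["waist_cm"]], 40.8)
  expect_equal(maternomorph:::.measure_one(av$tall, "height_cm"), 200,
               tolerance = 0.01)
  expect_equal(maternomorph:::.measure_one(av$big_breast, "chest_cm"), 200,
               tolerance = 0.02)
  expect_equal(maternomorph:::.measure_one(av$big_waist, "waist_cm"), 160,
               tolerance = 0.02)
  expect_equal(maternomorph:::.measure_one(av$big_hip, "hip_cm"), 180,
               tolerance = 0.02)
  expect_equal(maternomorph:::.measure_one(av$long_legs, "inseam_cm"), 120,
               tolerance = 0.02)
})

test_that("long-legs avatar has a longer inseam than thin", {
  av <- test_avatars()
  expect_gt(maternomorph:::.measure_one(av$long_legs, "inseam_cm"),
            maternomorph:::.measure_one(av$thin, "inseam_cm"))
})

test_that("morph targets stay local: big_breast leaves the waist at thin's", {
  av <- test_avatars()
  w_thin <- maternomorph:::.measure_one(av$thin, "waist_cm")
  w_bb <- maternomorph:::.measure_one(av$big_breast, "waist_cm")
  expect_lt(abs(w_bb - w_thin) / w_thin, 0.05)
})

test_that("meshes sit on the floor and the pregnant belly bulges forward", {
  av <- test_avatars()
  for (m in av) expect_gte(min(m$vertices[, "y"]), 0)
  # anterior (positive z) extent grows at abdomen level on pregnant_thin
  band <- av$thin$vertices[, "y"] > 95 & av$thin$vertices[, "y"] < 115
  expect_gt(max(av$pregnant_thin$vertices[band, "z"]),
            max(av$thin$vertices[band, "z"]) + 4)
})

test_that("too-low resolution is refused with a diagnostic", {
  expect_error(generate_synthetic_avatars(n_theta = 8), "generation failure")
  expect_error(generate_synthetic_avatars(ring_step_cm = 10), "generation failure")
})

test_that("avatar sets round-trip through an OBJ directory", {
  av <- generate_synthetic_avatars(n_theta = 16, ring_step_cm = 6, verify = FALSE)
  dir <- withr::local_tempdir()
  write_avatar_set(av, dir)
  back <- read_avatar_set(dir)
  expect_identical(names(back), names(av))
  expect_lt(max(abs(back$thin$vertices - av$thin$vertices)), 1e-5)
})
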