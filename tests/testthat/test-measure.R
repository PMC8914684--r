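test_that("cylinder and prism girths match the closed forms", {
  cyl <- make_cylinder(radius = 1, height = 10)
  sec <- slice_mesh(cyl, 5)
  expect_length(sec$loops, 1L)
  expect_equal(girth(sec, "torso"), 2 * pi, tolerance = 0.01)
  # 10 x 10 square prism: perimeter 40 exactly up to float noise
  sq <- rbind(c(-5, -5), c(5, -5), c(5, 5), c(-5, 5))
  prism <- make_prism(sq, 20)
  expect_equal(girth(slice_mesh(prism, 10), "torso"), 40, tolerance = 0.005 * 40)
  expect_error(slice_mesh(cyl, 11), "empty section")
})

test_that("girth converges with ring resolution on the cylinder", {
  errs <- vapply(c(16, 32, 64, 128), function(n) {
    g <- girth(slice_mesh(make_cylinder(1, 10, n_theta = n), 5), "torso")
    abs(g - 2 * pi)
  }, 0)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[4], 0.001)
})

test_that("hull semantics bridge concavities; polygon semantics do not", {
  # kidney-shaped loop: a circle with a deep inward notch
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  r <- 5 - 3 * exp(-((th - pi)^2) / 0.3)
  kidney <- cbind(r * cos(th), r * sin(th))
  prism <- make_prism(kidney, 10)
  sec <- slice_mesh(prism, 5)
  hull <- girth(sec, "torso")
  poly <- girth(sec, "torso", measure_config(method = "polygon"))
  expect_lt(hull, poly)
  expect_equal(hull, sec$loops[[1]]$hull_perimeter)
})

test_that("girth is invariant to y-rotation and xz-translation", {
  sq <- rbind(c(-5, -5), c(5, -5), c(5, 5), c(-5, 5))
  base <- girth(slice_mesh(make_prism(sq, 20), 10), "torso")
  ang <- 0.53
  rot <- sq %*% matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  expect_equal(girth(slice_mesh(make_prism(rot, 20), 10), "torso"), base,
               tolerance = 1e-10)
  shifted <- sweep(sq, 2, c(3, -7), "+")
  expect_equal(girth(slice_mesh(make_prism(shifted, 20), 10), "torso"), base,
               tolerance = 1e-10)
})

test_that("uniform scaling scales every measurement", {
  av <- test_avatars()
  m1 <- measure_all(av$thin)
  scaled <- mesh3(av$thin$vertices * 1.1, av$thin$faces)
  m2 <- measure_all(scaled)
  expect_equal(unclass(m2), unclass(m1) * 1.1, tolerance = 0.01)
})

test_that("measure_all reads the thin avatar's anchor dimensions", {
  m <- measure_all(test_avatars()$thin)
  expect_equal(unname(m[["waist_cm"]]), 40, tolerance = 0.02)
  expect_equal(unname(m[["chest_cm"]]), 57, tolerance = 0.02)
  expect_equal(unname(m[["hip_cm"]]), 68, tolerance = 0.02)
  expect_equal(unname(m[["inseam_cm"]]), 73, tolerance = 0.02)
  expect_equal(unname(m[["height_cm"]]), 165, tolerance = 0.001)
})

test_that("region selection errors are informative", {
  cyl <- make_cylinder(1, 10)
  expect_error(girth(slice_mesh(cyl, 5), "left_arm"), "left_arm")
})
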