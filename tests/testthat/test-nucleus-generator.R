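test_that("sphere ground truth matches the closed forms", {
  sp <- nucleus_shape_spec(semi_axes = c(5, 5, 5), psf_sigma = 0,
                           noise_model = "none", voxel_size = c(0.4, 0.4, 0.4))
  g <- generate_nucleus_image(sp)
  expect_equal(g$truth$volume_um3, 4 / 3 * pi * 125, tolerance = 1e-4)
  expect_equal(g$truth$area_um2, 4 * pi * 25, tolerance = 1e-4)
  expect_equal(g$truth$sphericity, 1, tolerance = 1e-4)
})

test_that("prolate spheroid ground truth matches the closed-form area", {
  g <- generate_nucleus_image(
    nucleus_shape_spec(semi_axes = c(5, 5, 10), psf_sigma = 0,
                       noise_model = "none", voxel_size = c(0.5, 0.5, 0.5)))
  a <- 5; cc <- 10
  e <- sqrt(1 - a^2 / cc^2)
  area <- 2 * pi * a^2 * (1 + (cc / (a * e)) * asin(e))
  vol <- 4 / 3 * pi * a^2 * cc
  psi <- pi^(1 / 3) * (6 * vol)^(2 / 3) / area   # = 0.92874
  expect_equal(g$truth$area_um2, area, tolerance = 1e-4)
  expect_equal(g$truth$sphericity, psi, tolerance = 1e-4)
  expect_lt(g$truth$sphericity, 1)
})

test_that("images are reproducible under a fixed seed and noise is applied", {
  sp <- nucleus_shape_spec(semi_axes = c(3, 3, 3), voxel_size = c(0.4, 0.4, 0.4),
                           seed = 17)
  a <- generate_nucleus_image(sp)$image$data
  b <- generate_nucleus_image(sp)$image$data
  expect_identical(a, b)
  expect_true(all(a == round(a)))  # Poisson counts
  sp2 <- sp; sp2$seed <- 18L
  expect_false(identical(a, generate_nucleus_image(sp2)$image$data))
})

test_that("voxelized mask volume converges to the analytic volume with resolution", {
  vols <- vapply(c(0.5, 0.25), function(v) {
    m <- ellipsoid_mask(c(4, 4, 4), rep(v, 3))
    sum(m$labels) * v^3
  }, 0)
  truth <- 4 / 3 * pi * 64
  err <- abs(vols - truth) / truth
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.01)
})

test_that("a solid too large for an explicit extent is rejected", {
  expect_error(nucleus_shape_spec(semi_axes = c(10, 10, 10),
                                  voxel_size = c(0.5, 0.5, 0.5),
                                  dim = c(16L, 16L, 16L)),
               "does not fit")
})

test_that("deformed shapes have lower sphericity ground truth", {
  g <- generate_nucleus_image(
    nucleus_shape_spec(semi_axes = c(4, 4, 4), psf_sigma = 0,
                       noise_model = "none", voxel_size = c(0.4, 0.4, 0.4),
                       deformation_amplitude = 0.3))
  expect_lt(g$truth$sphericity, 0.99)
  expect_gt(g$truth$sphericity, 0.8)
})
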