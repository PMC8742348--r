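test_that("sphericity formula reproduces analytic cases", {
  expect_equal(sphericity(1, 6), (pi / 6)^(1 / 3), tolerance = 1e-12) # unit cube
  r <- 3.7
  expect_equal(sphericity(4 / 3 * pi * r^3, 4 * pi * r^2), 1, tolerance = 1e-12)
})

test_that("a high-resolution voxelized sphere measures sphericity within 0.02 of 1", {
  m <- ellipsoid_mask(c(20, 20, 20), c(1, 1, 1), margin = 3)
  rec <- measure(m)
  expect_lt(abs(rec$sphericity - 1), 0.02)
  expect_lt(abs(rec$volume_um3 - 4 / 3 * pi * 8000) / (4 / 3 * pi * 8000), 0.01)
  expect_false(rec$border_flag)
})

test_that("sphericity is invariant under isotropic voxel rescaling", {
  m <- ellipsoid_mask(c(4, 4, 4), c(0.4, 0.4, 0.4))
  r1 <- measure(m)
  r2 <- measure(nucleus_mask(m$labels, m$voxel_size * 3))
  expect_equal(r2$sphericity, r1$sphericity, tolerance = 1e-10)
  expect_equal(r2$volume_um3, r1$volume_um3 * 27, tolerance = 1e-10)
})

test_that("sphericity decreases monotonically along an elongation sweep", {
  psis <- vapply(c(1, 1.5, 2, 3), function(q) {
    a <- 4 / q^(1 / 3)            # fixed volume: a^2 c = const, c = q a
    m <- ellipsoid_mask(c(a, a, q * a), rep(0.25, 3))
    measure(m)$sphericity
  }, 0)
  expect_true(all(diff(psis) < 0))
})

test_that("volume is additive over labels", {
  m <- ellipsoid_mask(c(2.5, 2.5, 2.5), c(0.4, 0.4, 0.4))
  d <- dim(m$labels)
  two <- array(0L, d + c(d[1], 0L, 0L))
  two[seq_len(d[1]), , ] <- m$labels
  two[d[1] + seq_len(d[1]), , ] <- 2L * m$labels
  mk <- nucleus_mask(two, m$voxel_size)
  rec <- measure(mk)
  expect_equal(sum(rec$volume_um3), sum(two > 0) * prod(m$voxel_size))
  expect_equal(nrow(rec), 2)
})

test_that("mesh surface area converges to the sphere area with resolution", {
  errs <- vapply(c(0.5, 0.25), function(v) {
    m <- ellipsoid_mask(c(4, 4, 4), rep(v, 3))
    abs(measure(m)$area_um2 - 4 * pi * 16) / (4 * pi * 16)
  }, 0)
  expect_lt(errs[2], errs[1])
  expect_lt(errs[2], 0.02)
})

test_that("labels touching the border are flagged as truncated", {
  m <- ellipsoid_mask(c(3, 3, 3), c(0.4, 0.4, 0.4))
  lab <- m$labels[, , 9:dim(m$labels)[3]]   # crop through the middle
  rec <- measure(nucleus_mask(lab, m$voxel_size))
  expect_true(rec$border_flag)
})
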