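test_that("a noiseless binary sphere is segmented exactly", {
  m <- ellipsoid_mask(c(3, 3, 3), c(0.4, 0.4, 0.4))
  img <- nucleus_image(m$labels * 100, m$voxel_size)
  seg <- segment_nuclei(img, min_volume = 10, max_volume = 4000)
  expect_identical(seg$labels > 0, m$labels > 0)
  expect_equal(max(seg$labels), 1L)
})

test_that("two separated spheres give exactly two labels", {
  d <- c(40L, 24L, 24L)
  x <- array(0, d)
  ctr <- function(i0, r) {
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
      if ((i - i0)^2 + (j - 12)^2 + (k - 12)^2 <= r^2) x[i, j, k] <<- 100
  }
  ctr(11, 6); ctr(30, 6)
  seg <- segment_nuclei(nucleus_image(x, c(0.5, 0.5, 0.5)),
                        min_volume = 10, max_volume = 4000)
  expect_equal(max(seg$labels), 2L)
})

test_that("the denoise/segment chain recovers the generator volume within 5%", {
  g <- generate_nucleus_image(
    nucleus_shape_spec(semi_axes = c(4, 4, 4), peak_intensity = 100,
                       background = 5, psf_sigma = 0.3,
                       voxel_size = c(0.25, 0.25, 0.25), seed = 23))
  img <- denoise(g$image)
  rec <- measure(segment_nuclei(img))
  expect_equal(nrow(rec), 1)
  expect_lt(abs(rec$volume_um3 - g$truth$volume_um3) / g$truth$volume_um3, 0.05)
})

test_that("interior holes are filled slice-wise", {
  m <- ellipsoid_mask(c(3, 3, 3), c(0.4, 0.4, 0.4))
  core <- ellipsoid_mask(c(1.2, 1.2, 1.2), c(0.4, 0.4, 0.4))
  d <- dim(m$labels); dc <- dim(core$labels)
  off <- (d - dc) %/% 2
  hollow <- m$labels
  hollow[off[1] + seq_len(dc[1]), off[2] + seq_len(dc[2]),
         off[3] + seq_len(dc[3])] <-
    hollow[off[1] + seq_len(dc[1]), off[2] + seq_len(dc[2]),
           off[3] + seq_len(dc[3])] - core$labels
  img <- nucleus_image(hollow * 100, m$voxel_size)
  seg <- segment_nuclei(img, min_volume = 10, max_volume = 4000)
  expect_equal(sum(seg$labels > 0), sum(m$labels > 0))
})

test_that("empty or fully gated foreground raises 'no nuclei found'", {
  x <- array(0, c(10, 10, 10)); x[5, 5, 5] <- 1
  img <- nucleus_image(x, c(0.5, 0.5, 0.5))
  expect_error(segment_nuclei(img, min_volume = 50, max_volume = 4000),
               "no nuclei found")
})
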