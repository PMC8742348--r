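# brute-force symmetric-normalized estimator, kept deliberately simple
brute_acf <- function(x, lags_bins) {
  n <- length(x)
  vapply(lags_bins, function(k) {
    a <- x[1:(n - k)]
    b <- x[(k + 1):n]
    mean(a * b) / (mean(a) * mean(b)) - 1
  }, 0)
}

test_that("multi-tau equals the direct brute-force estimator on a 4096-bin trace", {
  set.seed(101)
  x <- rpois(4096, 4) + rep(c(0L, 2L, 4L, 2L), length.out = 4096)
  tr <- intensity_trace(x, 1e-4)
  cv <- autocorrelate(tr, "multi_tau")
  ref <- brute_acf(as.numeric(x), round(cv$lags / 1e-4))
  expect_lt(max(abs(cv$G - ref) / pmax(abs(ref), 1e-8)), 1e-10)

  dv <- autocorrelate(tr, "direct", max_lag = 64)
  shared <- dv$lags %in% cv$lags
  expect_equal(dv$G[shared], cv$G[cv$lags %in% dv$lags], tolerance = 1e-12)
})

test_that("white-noise traces have zero autocorrelation at positive lags", {
  set.seed(7)
  m <- replicate(20, {
    tr <- intensity_trace(rpois(20000, 3), 1e-5)
    mean(autocorrelate(tr)$G)
  })
  se <- sd(m) / sqrt(length(m))
  expect_lt(abs(mean(m)), 4 * se)
})

test_that("period-2 trace alternates correlation sign with lag parity", {
  tr <- intensity_trace(rep(c(2L, 8L), 500), 1e-3)
  cv <- autocorrelate(tr, "direct", max_lag = 4)
  expect_lt(cv$G[1], 0)
  expect_gt(cv$G[2], 0)
  expect_gt(cv$G[2], cv$G[1])
})

test_that("count scaling leaves G unchanged and offsets shrink |G|", {
  set.seed(11)
  x <- rpois(5000, 2) + rep(c(0L, 3L), 2500)
  g1 <- autocorrelate(intensity_trace(x, 1e-4))$G
  g3 <- autocorrelate(intensity_trace(3L * x, 1e-4))$G
  expect_equal(g3, g1, tolerance = 1e-12)
  goff <- autocorrelate(intensity_trace(x + 5L, 1e-4))$G
  expect_true(all(abs(goff) < abs(g1)))
})

test_that("degenerate traces are rejected", {
  expect_error(autocorrelate(intensity_trace(rep(0L, 100), 1e-4)), "zero mean")
  expect_error(autocorrelate(intensity_trace(rep(3L, 100), 1e-4)), "zero variance")
})

test_that("multi-tau lag layout is increasing with doubling spacing", {
  lags <- multi_tau_lags(4096, m = 16, ratio = 2)
  expect_true(all(diff(lags) > 0))
  expect_identical(lags[1:16], 1:16L)
  expect_true(all(diff(lags[lags > 16 & lags <= 32]) == 2))
  expect_true(all(diff(lags[lags > 32 & lags <= 64]) == 4))
  expect_lte(max(lags), 4096)
})

test_that("curve averaging: identity, symmetry, and SD scaling", {
  cv <- generate_acf_curves(mix_params(), fit_lag_grid(1e-4, 1), 0.01, 1,
                            seed = 5)[[1]]
  av <- average_curves(list(cv, cv))
  expect_equal(av$G, cv$G)
  expect_true(all(av$sd == 0))
  expect_equal(av$n_traces_averaged, 2L)

  neg <- correlation_curve(cv$lags, -cv$G)
  expect_true(all(abs(average_curves(list(cv, neg))$G) < 1e-15))

  other <- correlation_curve(cv$lags[-1], cv$G[-1])
  expect_error(average_curves(list(cv, other)), "identical lag grid")
  expect_error(average_curves(list()), "empty")

  # per-lag SD of averaged replicates reflects the injected noise scale
  cs <- generate_acf_curves(mix_params(), fit_lag_grid(1e-4, 1), 0.02, 100,
                            seed = 8)
  av100 <- average_curves(cs)
  expect_lt(abs(mean(av100$sd) - 0.02) / 0.02, 0.3)
})
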