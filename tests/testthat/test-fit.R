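test_that("noiseless curves are recovered to high relative accuracy", {
  p <- mix_params()
  cv <- generate_acf_curves(p, fit_lag_grid(), 0, 1)[[1]]
  fit <- fit_acf(cv, omega = 5)
  nm <- c("N", "f_D", "f_short", "f_long", "tau_D", "tau_short", "tau_long")
  rel <- abs(unlist(fit$params[nm]) - unlist(p[nm])) / unlist(p[nm])
  expect_lt(max(rel), 1e-6)
  expect_true(fit$converged)
  # refitting the model curve of a fitted result reproduces that result
  cv2 <- generate_acf_curves(fit$params, cv$lags, 0, 1)[[1]]
  fit2 <- fit_acf(cv2, omega = 5)
  rel2 <- abs(unlist(fit2$params[nm]) - unlist(fit$params[nm])) /
    unlist(fit$params[nm])
  expect_lt(max(rel2), 1e-5)
})

test_that("swapped residence-time initialization reaches the ordered optimum", {
  cv <- generate_acf_curves(mix_params(), fit_lag_grid(), 0.005, 1,
                            seed = 3)[[1]]
  f1 <- fit_acf(cv, omega = 5)
  f2 <- fit_acf(cv, omega = 5, tau_short_grid = 2, tau_long_grid = 0.02)
  expect_lt(f2$params$tau_short, f2$params$tau_long)
  expect_equal(f2$params$tau_long, f1$params$tau_long, tolerance = 1e-3)
  expect_equal(f2$params$f_long, f1$params$f_long, tolerance = 1e-3)
})

test_that("fitted fractions satisfy the simplex constraint to machine precision", {
  cs <- generate_acf_curves(mix_params(), fit_lag_grid(), 0.02, 4, seed = 21)
  for (cv in cs) {
    f <- fit_acf(cv, omega = 5)$params
    expect_equal(f$f_D + f$f_short + f$f_long, 1, tolerance = 1e-12)
    expect_equal(1 / f$tau_short, fit_acf(cv, omega = 5)$k_off_short)
  }
})

test_that("fit rejects unusable curves", {
  cv <- generate_acf_curves(mix_params(), fit_lag_grid(), 0, 1)[[1]]
  flat <- correlation_curve(cv$lags, -cv$G)
  expect_error(fit_acf(flat, omega = 5), "non-positive")
  short <- correlation_curve(cv$lags[1:5], cv$G[1:5])
  expect_error(fit_acf(short, omega = 5), "at least 10 lags")
})

test_that("bootstrap SE matches the asymptotic SE of the median", {
  expect_equal(bootstrap_se(rep(5, 50), median, 500, seed = 1)$se, 0)
  # single-sample bootstrap SEs of a median fluctuate ~20% at n = 400, so
  # the asymptotic oracle 1.2533 sigma/sqrt(n) is checked on a 12-sample mean
  target <- 1.2533 / sqrt(400)
  ses <- vapply(1:12, function(s) {
    set.seed(1000 + s)
    bootstrap_se(rnorm(400), median, 2000, seed = s)$se
  }, 0)
  expect_lt(abs(mean(ses) - target) / target, 0.15)
  set.seed(99)
  x <- rnorm(400)
  bs <- bootstrap_se(x, median, 500, seed = 11)
  expect_equal(bs$variance, bs$se^2)
  expect_identical(bs$se, bootstrap_se(x, median, 500, seed = 11)$se)
  expect_error(bootstrap_se(numeric(0), median), "empty")
  expect_error(bootstrap_se(c(1, 2), median, n_reps = 1), "at least 2")
})
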