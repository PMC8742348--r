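test_that("no emission source yields an all-zero trace", {
  cfg <- trace_sim_config(diffusion_coefficient = 10, N = 1, brightness = 0,
                          background_rate = 0, duration = 0.01,
                          bin_width = 1e-5, seed = 1)
  expect_true(all(simulate_trace(cfg)$trace$counts == 0L))
})

test_that("traces are bit-identical under a fixed seed", {
  cfg <- trace_sim_config(diffusion_coefficient = 10, N = 1, brightness = 2e4,
                          binding_classes = list(c(5, 50), c(1, 2)),
                          duration = 0.05, bin_width = 1e-5, seed = 42)
  expect_identical(simulate_trace(cfg)$trace$counts,
                   simulate_trace(cfg)$trace$counts)
})

test_that("mean count rate matches the uniform-emitter closed form", {
  # <rate> = eps * N / 2^{3/2} + background for N in the e^-2 focal volume
  rates <- vapply(1:10, function(s) {
    cfg <- trace_sim_config(diffusion_coefficient = 10, N = 2, brightness = 3e4,
                            background_rate = 500, duration = 0.3,
                            bin_width = 1e-5, seed = 300 + s)
    tr <- simulate_trace(cfg)$trace
    mean(tr$counts) / tr$bin_width
  }, 0)
  expected <- 3e4 * 2 / 2^(3 / 2) + 500
  se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - expected), 3 * se)
})

test_that("counts are non-negative integers scaling linearly with brightness", {
  mk <- function(eps, s) {
    cfg <- trace_sim_config(diffusion_coefficient = 10, N = 2, brightness = eps,
                            duration = 0.2, bin_width = 1e-5, seed = s)
    simulate_trace(cfg)$trace$counts
  }
  tot1 <- vapply(1:6, function(s) sum(mk(2e4, s)), 0)
  tot2 <- vapply(1:6, function(s) sum(mk(4e4, s + 100)), 0)
  expect_true(all(tot1 >= 0))
  ratio <- mean(tot2) / mean(tot1)
  se_ratio <- ratio * sqrt((sd(tot2) / mean(tot2))^2 + (sd(tot1) / mean(tot1))^2) / sqrt(6)
  expect_lt(abs(ratio - 2), 4 * se_ratio)
})

test_that("implied ground truth follows the rate algebra", {
  cfg <- trace_sim_config(diffusion_coefficient = 20, w_r = 0.25, N = 2,
                          binding_classes = list(c(30, 50), c(0.8, 2)),
                          duration = 0.1, bin_width = 1e-5)
  tru <- implied_fcs_params(cfg)
  expect_equal(tru$tau_D, 0.25^2 / (4 * 20))
  expect_equal(tru$tau_short, 1 / 50)
  expect_equal(tru$tau_long, 1 / 2)
  r <- c(30 / 50, 0.8 / 2)
  expect_equal(tru$f_D, 1 / (1 + sum(r)))
  expect_equal(tru$f_short, r[1] / (1 + sum(r)))
  expect_equal(tru$f_long, r[2] / (1 + sum(r)))
  # amplitude convention: configured focal-volume occupancy over 2^{3/2}
  expect_equal(tru$N, 2 / 2^(3 / 2))
})

test_that("configuration validation enforces the documented limits", {
  expect_error(trace_sim_config(10, duration = 1e-4, bin_width = 1e-5),
               "100 bin widths")
  expect_error(trace_sim_config(10, duration = 1,
                                binding_classes = list(c(1, 2), c(1, 1), c(1, 0.5))),
               "two binding classes")
  expect_error(trace_sim_config(10, duration = 1,
                                binding_classes = list(c(1, 2), c(1, 50))),
               "short-lived first")
  expect_error(trace_sim_config(10, duration = 1, bin_width = 1e-2,
                                binding_classes = list(c(100, 200))),
               "exceeds 0.1")
})

test_that("noiseless synthetic curves equal the model exactly and are seeded", {
  p <- mix_params()
  lags <- fit_lag_grid(1e-4, 1)
  cv <- generate_acf_curves(p, lags, 0, 2)
  expect_equal(cv[[1]]$G, evaluate_acf_model(p, lags), tolerance = 1e-15)
  expect_equal(cv[[2]]$G, cv[[1]]$G)
  a <- generate_acf_curves(p, lags, 0.05, 3, seed = 77)
  b <- generate_acf_curves(p, lags, 0.05, 3, seed = 77)
  expect_identical(a, b)
  expect_error(generate_acf_curves(p, lags, -0.1, 1), "non-negative")
  expect_error(generate_acf_curves(p, numeric(0), 0.1, 1))
})

test_that("noisy curve ensemble converges to the noiseless model", {
  p <- mix_params()
  lags <- fit_lag_grid(1e-3, 1)
  cs <- generate_acf_curves(p, lags, 0.03, 1000, seed = 13)
  mu <- colMeans(do.call(rbind, lapply(cs, `[[`, "G")))
  se <- 0.03 / sqrt(1000)
  expect_true(all(abs(mu - evaluate_acf_model(p, lags)) < 4.5 * se))
})
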