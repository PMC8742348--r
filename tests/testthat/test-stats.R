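fake_group <- function(label, center, variance, n = 10) {
  structure(list(label = label, values = rep(center, n), center = center,
                 se = sqrt(variance), variance = variance, n = n,
                 mode = "median"),
            class = "group_stats")
}

test_that("median test follows the two-sided normal formula", {
  expect_equal(median_test(fake_group("a", 5, 0.2),
                           fake_group("b", 5, 0.3))$p_value, 1)
  # z = 1.959964 is the two-sided 5% point
  cmp <- median_test(fake_group("a", 0, 0.5),
                     fake_group("b", 1.959964, 0.5))
  expect_equal(cmp$z, 1.959964, tolerance = 1e-6)
  expect_equal(cmp$p_value, 0.05, tolerance = 1e-4)
  # symmetry in group order
  expect_equal(median_test(fake_group("b", 3, 0.1), fake_group("a", 1, 0.4))$p_value,
               median_test(fake_group("a", 1, 0.4), fake_group("b", 3, 0.1))$p_value)
})

test_that("p decreases monotonically with the median difference", {
  ps <- vapply(c(0.5, 1, 2, 4), function(d)
    median_test(fake_group("a", 0, 0.3), fake_group("b", d, 0.3))$p_value, 0)
  expect_true(all(diff(ps) < 0))
})

test_that("degenerate zero-variance comparisons are handled explicitly", {
  expect_warning(cmp <- median_test(fake_group("a", 1, 0), fake_group("b", 2, 0)),
                 "zero")
  expect_equal(cmp$p_value, 0)
  expect_equal(median_test(fake_group("a", 2, 0), fake_group("b", 2, 0))$p_value, 1)
})

test_that("p-values are invariant under a common shift of both groups", {
  set.seed(31)
  x <- rnorm(40, 10, 2); y <- rnorm(40, 11, 2)
  p1 <- median_test(group_stats("a", x, seed = 5), group_stats("b", y, seed = 6))$p_value
  p2 <- median_test(group_stats("a", x + 100, seed = 5),
                    group_stats("b", y + 100, seed = 6))$p_value
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("radius increment follows the cube-root rule", {
  expect_equal(radius_increment(100, 100), 0)
  expect_equal(radius_increment(100, 119.1016), 6, tolerance = 1e-4)
  expect_equal(radius_increment(100, 109.2727), 3, tolerance = 1e-4)
  for (k in c(0.5, 0.9, 1.3, 2)) # exact identity
    expect_equal(radius_increment(7, 7 * k^3), (k - 1) * 100, tolerance = 1e-10)
  expect_error(radius_increment(-1, 2))
})

test_that("group summaries compute medians and bootstrap SEs", {
  tab <- data.frame(v = c(1, 2, 3, 4, 5, 1, 1, 1, 1),
                    g = rep(c("a", "b"), c(5, 4)))
  gs <- summarize_groups(tab, "v", "g", n_boot = 200, seed = 4)
  expect_equal(gs$a$center, 3)
  expect_equal(gs$b$center, 1)
  expect_equal(gs$b$se, 0)
  expect_error(summarize_groups(tab, "nope", "g"), "unknown value column")
  expect_error(summarize_groups(data.frame(v = 1, g = "a"), "v", "g"),
               "at least 2")
  set.seed(12)
  tab2 <- data.frame(v = rnorm(400), g = "a")
  s <- summarize_groups(tab2, "v", "g", n_boot = 2000, seed = 8)$a
  expect_lt(abs(s$se - 1.2533 / 20) / (1.2533 / 20), 0.15)
})
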