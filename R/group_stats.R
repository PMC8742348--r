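#' Per-group summary with bootstrap uncertainty
#'
#' Summarizes one group of per-cell measurements by its median (or mean) with
#' a bootstrap standard error and variance of that statistic
#' (see [bootstrap_se]).
#'
#' @param label group label.
#' @param values numeric measurements (length >= 2).
#' @param mode `"median"` (default, used for morphometry) or `"mean"` (used
#'   for FCS parameters).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed optional integer seed.
#' @return An object of class `group_stats` with fields `label`, `values`,
#'   `center`, `se`, `variance`, `n`, `mode`.
#' @export
group_stats <- function(label, values, mode = c("median", "mean"),
                        n_boot = 1000L, seed = NULL) {
  mode <- match.arg(mode)
  values <- as.numeric(values)
  if (length(values) < 2) stop("group needs at least 2 values")
  stat <- if (mode == "median") median else mean
  bs <- bootstrap_se(values, stat, n_reps = n_boot, seed = seed)
  structure(list(label = label, values = values, center = stat(values),
                 se = bs$se, variance = bs$variance,
                 n = length(values), mode = mode),
            class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat(sprintf("Group '%s': %s = %.4g +/- %.3g (bootstrap SE), n = %d\n",
              x$label, x$mode, x$center, x$se, x$n))
  invisible(x)
}

#' Summarize groups of a measurement table
#'
#' @param table data.frame of per-cell measurements.
#' @param value_column name of the numeric column to summarize.
#' @param group_column name of the grouping column.
#' @param mode summary statistic, `"median"` or `"mean"`.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed; per-group seeds are derived deterministically.
#' @return Named list of [group_stats], one per group level.
#' @export
summarize_groups <- function(table, value_column, group_column,
                             mode = c("median", "mean"), n_boot = 1000L,
                             seed = NULL) {
  mode <- match.arg(mode)
  if (!value_column %in% names(table)) stop("unknown value column: ", value_column)
  if (!group_column %in% names(table)) stop("unknown group column: ", group_column)
  groups <- split(table[[value_column]], table[[group_column]])
  out <- list()
  for (i in seq_along(groups)) {
    g <- names(groups)[i]
    s <- if (is.null(seed)) NULL else derive_seed(seed, paste0("boot_", g), i)
    out[[g]] <- group_stats(g, groups[[i]], mode = mode, n_boot = n_boot,
                            seed = s)
  }
  out
}

#' Compare two group medians (or means) by the bootstrap-variance z-test
#'
#' Computes `z = |center(g1) - center(g2)| / sqrt(var(g1) + var(g2))` with
#' the bootstrap variances of the group statistics, and the two-sided normal
#' p-value `p = 2 (1 - F(z))` where `F` is the standard normal CDF. The test
#' is symmetric in group order.
#'
#' @param g1,g2 [group_stats] objects (same `mode`).
#' @param alpha significance level (default 0.05).
#' @return An object of class `comparison_result`: `pair`, `delta`
#'   (absolute difference of centers), `z`, `p_value`, `significant`, `alpha`.
#' @export
median_test <- function(g1, g2, alpha = 0.05) {
  stopifnot(inherits(g1, "group_stats"), inherits(g2, "group_stats"),
            alpha > 0, alpha < 1)
  delta <- abs(g1$center - g2$center)
  v <- g1$variance + g2$variance
  if (v == 0) {
    if (delta > 0) {
      warning("both bootstrap variances are zero; p degenerates to 0")
      z <- Inf; p <- 0
    } else {
      z <- 0; p <- 1
    }
  } else {
    z <- delta / sqrt(v)
    p <- 2 * (1 - pnorm(z))
  }
  structure(list(pair = c(g1$label, g2$label), delta = delta, z = z,
                 p_value = p, significant = p < alpha, alpha = alpha),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s vs %s: |delta| = %.4g, z = %.3f, p = %.4g (%s at alpha = %g)\n",
              x$pair[1], x$pair[2], x$delta, x$z, x$p_value,
              if (x$significant) "significant" else "not significant", x$alpha))
  invisible(x)
}

#' Percent radius increment implied by a volume change
#'
#' Under volume scaling with the cube of the radius, a volume ratio `k^3`
#' maps to a radius change of `(k - 1) * 100` percent:
#' `((v_treated / v_reference)^{1/3} - 1) * 100`.
#'
#' @param volume_reference,volume_treated volumes (> 0), e.g. group medians.
#' @return Percent change in equivalent radius.
#' @examples
#' radius_increment(100, 100 * 1.06^3) # 6
#' @export
radius_increment <- function(volume_reference, volume_treated) {
  stopifnot(all(volume_reference > 0), all(volume_treated > 0))
  ((volume_treated / volume_reference)^(1 / 3) - 1) * 100
}
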