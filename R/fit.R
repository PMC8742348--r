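# Fitting of the diffusion + two-binding-population ACF model.
#
# Free parameters are optimized on an unconstrained scale: log N, log tau's,
# and softmax logits for the population fractions (diffusion is the logit
# gauge), which keeps fractions on the simplex by construction.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

num_jacobian <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

# map unconstrained theta -> fcs_params, given the model layout
theta_to_params <- function(theta, layout) {
  i <- 1
  N <- exp(theta[i]); i <- i + 1
  tau_D <- if (is.na(layout$fixed_tau_D)) { v <- exp(theta[i]); i <- i + 1; v
  } else layout$fixed_tau_D
  a_s <- if (layout$short) { v <- theta[i]; i <- i + 1; v } else -Inf
  a_l <- if (layout$long)  { v <- theta[i]; i <- i + 1; v } else -Inf
  tau_s <- if (layout$short) { v <- exp(theta[i]); i <- i + 1; v } else layout$tau_s0
  tau_l <- if (layout$long)  { v <- exp(theta[i]); i <- i + 1; v } else layout$tau_l0
  z <- exp(c(0, a_s, a_l) - max(0, a_s, a_l))
  f <- z / sum(z)
  list(N = N, f_D = f[1], f_short = f[2], f_long = f[3],
       tau_D = tau_D, omega = layout$omega,
       tau_short = tau_s, tau_long = tau_l)
}

model_from_plain <- function(p, lags) {
  diff_term <- p$f_D / ((1 + lags / p$tau_D) *
                          sqrt(1 + lags / (p$omega^2 * p$tau_D)))
  bind_term <- p$f_short * exp(-lags / p$tau_short) +
    p$f_long * exp(-lags / p$tau_long)
  (diff_term + bind_term) / (2^(3 / 2) * p$N)
}

#' Fit the diffusion + two-binding-population model to a correlation curve
#'
#' Weighted least squares with the population fractions constrained to the
#' simplex (softmax parameterization), residence times fitted on a log scale,
#' and multi-start initialization over a log-spaced grid of
#' `(tau_short, tau_long)` seeds (best residual sum of squares wins, ties
#' broken by the smaller `tau_long`). The waist ratio `omega` is a fixed
#' calibration input, never free. After optimization the two binding
#' components are ordered so `tau_short < tau_long`. Standard errors come
#' from the Gauss-Newton curvature at the optimum, mapped to the natural
#' scale by the delta method.
#'
#' @param curve a [correlation_curve]; at least 10 lags spanning at least
#'   3 decades.
#' @param omega fixed axial/radial waist ratio (default 5).
#' @param components model components to include: any of `"short"`,
#'   `"long"` in addition to the always-present `"diffusion"`.
#' @param tau_D optional fixed diffusion time (s); if `NULL` it is fitted.
#' @param lag_range fit window in seconds; default
#'   `c(min(lags), duration / 10)` when the curve knows its acquisition
#'   duration (long-lag estimates on finite traces are biased), else the full
#'   grid.
#' @param weights per-lag weights; default `1/sd` when the curve carries
#'   positive per-lag standard deviations, else uniform.
#' @param tau_short_grid,tau_long_grid multi-start seed grids (s).
#' @return A `fit_result` list: `params` ([fcs_params]), `se` (named vector
#'   of standard errors on the natural scale), `k_off_short`, `k_off_long`,
#'   `rss`, `converged`, `n_restarts_used`, `n_lags_fit`.
#' @export
fit_acf <- function(curve, omega = 5,
                    components = c("diffusion", "short", "long"),
                    tau_D = NULL, lag_range = NULL, weights = NULL,
                    tau_short_grid = 10^seq(-3, -1, length.out = 3),
                    tau_long_grid = 10^seq(-1, 1, length.out = 3)) {
  stopifnot(inherits(curve, "correlation_curve"), omega > 0)
  components <- match.arg(components, c("diffusion", "short", "long"),
                          several.ok = TRUE)
  use_short <- "short" %in% components
  use_long <- "long" %in% components

  if (is.null(lag_range)) {
    hi <- if (is.finite(curve$duration %||% NA_real_)) curve$duration / 10 else max(curve$lags)
    lag_range <- c(min(curve$lags), hi)
  }
  keep <- curve$lags >= lag_range[1] & curve$lags <= lag_range[2]
  lags <- curve$lags[keep]
  G <- curve$G[keep]
  if (length(lags) < 10) stop("need at least 10 lags in the fit window")
  if (log10(max(lags) / min(lags)) < 3)
    warning("lag grid spans fewer than 3 decades; fit may be ill-conditioned")
  amp <- mean(G[seq_len(min(3, length(G)))])
  if (amp <= 0) stop("curve amplitude is non-positive; nothing to fit")

  w <- if (!is.null(weights)) {
    stopifnot(length(weights) == length(curve$lags))
    weights[keep]
  } else if (!is.null(curve$sd) && all(curve$sd[keep] > 0)) {
    1 / curve$sd[keep]
  } else rep(1, length(lags))
  w <- w / mean(w)

  layout <- list(fixed_tau_D = if (is.null(tau_D)) NA_real_ else tau_D,
                 short = use_short, long = use_long, omega = omega,
                 tau_s0 = 1e-3, tau_l0 = 1)

  obj <- function(theta) {
    p <- theta_to_params(theta, layout)
    r <- model_from_plain(p, lags) - G
    sum(w * r * r)
  }

  N0 <- max(1 / (2^(3 / 2) * amp), 1e-3)
  tauD0 <- if (is.null(tau_D)) {
    # lag where the curve first drops below half amplitude
    below <- which(G < amp / 2)
    if (length(below)) lags[below[1]] else stats::median(lags)
  } else tau_D

  starts <- list()
  ts_grid <- if (use_short) tau_short_grid else NA_real_
  tl_grid <- if (use_long) tau_long_grid else NA_real_
  for (ts in ts_grid) for (tl in tl_grid) {
    th <- log(N0)
    if (is.null(tau_D)) th <- c(th, log(tauD0))
    if (use_short) th <- c(th, 0)
    if (use_long) th <- c(th, 0)
    if (use_short) th <- c(th, log(ts))
    if (use_long) th <- c(th, log(tl))
    starts[[length(starts) + 1]] <- list(theta = th, tl = if (is.na(tl)) Inf else tl)
  }

  best <- NULL
  n_used <- 0L
  for (s in starts) {
    n_used <- n_used + 1L
    fit <- tryCatch({
      f1 <- optim(s$theta, obj, method = "BFGS",
                  control = list(maxit = 500, reltol = 1e-12))
      # simplex polish: BFGS stalls near machine-zero residuals
      f2 <- optim(f1$par, obj,
                  control = list(maxit = 2000, reltol = 1e-15))
      out <- if (f2$value < f1$value) f2 else f1
      # converged if either stage reports convergence at the shared optimum
      out$convergence <- min(f1$convergence, f2$convergence)
      out
    }, error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    cand <- list(fit = fit, tl = s$tl)
    if (is.null(best) || fit$value < best$fit$value - 1e-15 ||
        (abs(fit$value - best$fit$value) <= 1e-15 && cand$tl < best$tl))
      best <- cand
  }
  if (is.null(best))
    return(structure(list(params = NULL, se = NULL, k_off_short = NA_real_,
                          k_off_long = NA_real_, rss = NA_real_,
                          converged = FALSE, n_restarts_used = n_used,
                          n_lags_fit = length(lags)),
                     class = "fit_result"))

  theta_hat <- best$fit$par
  p <- theta_to_params(theta_hat, layout)

  # order the binding components: tau_short < tau_long
  if (use_short && use_long && p$tau_short > p$tau_long) {
    p[c("tau_short", "tau_long")] <- p[c("tau_long", "tau_short")]
    p[c("f_short", "f_long")] <- p[c("f_long", "f_short")]
  }

  # natural-scale SEs: Gauss-Newton covariance + delta method
  nat <- function(theta) {
    q <- theta_to_params(theta, layout)
    c(N = q$N, f_D = q$f_D, f_short = q$f_short, f_long = q$f_long,
      tau_D = q$tau_D, tau_short = q$tau_short, tau_long = q$tau_long)
  }
  se <- setNames(rep(NA_real_, 7),
                 c("N", "f_D", "f_short", "f_long", "tau_D", "tau_short", "tau_long"))
  npar <- length(theta_hat)
  dof <- length(lags) - npar
  if (dof > 0) {
    H <- tryCatch(optimHess(theta_hat, obj), error = function(e) NULL)
    if (!is.null(H)) {
      sigma2 <- best$fit$value / dof
      cov_theta <- tryCatch(2 * sigma2 * solve(H), error = function(e) NULL)
      if (!is.null(cov_theta)) {
        Jn <- num_jacobian(nat, theta_hat)
        v <- diag(Jn %*% cov_theta %*% t(Jn))
        v[v < 0] <- NA_real_
        se_raw <- sqrt(v)
        names(se_raw) <- names(nat(theta_hat))
        if (use_short && use_long &&
            theta_to_params(theta_hat, layout)$tau_short >
            theta_to_params(theta_hat, layout)$tau_long) {
          se_raw[c("tau_short", "tau_long")] <- se_raw[c("tau_long", "tau_short")]
          se_raw[c("f_short", "f_long")] <- se_raw[c("f_long", "f_short")]
        }
        se <- se_raw
      }
    }
  }

  params <- fcs_params(N = p$N, f_D = p$f_D, f_short = p$f_short,
                       f_long = p$f_long, tau_D = p$tau_D, omega = omega,
                       tau_short = min(p$tau_short, p$tau_long * (1 - 1e-12)),
                       tau_long = p$tau_long)
  structure(list(params = params, se = se,
                 k_off_short = 1 / params$tau_short,
                 k_off_long = 1 / params$tau_long,
                 rss = best$fit$value,
                 converged = best$fit$convergence == 0,
                 n_restarts_used = n_used,
                 n_lags_fit = length(lags)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  if (is.null(x$params)) {
    cat("ACF fit: did not converge (", x$n_restarts_used, "restarts )\n")
    return(invisible(x))
  }
  cat(sprintf("ACF fit (%s, RSS = %.4g, %d lags):\n",
              if (x$converged) "converged" else "NOT converged",
              x$rss, x$n_lags_fit))
  print(x$params)
  cat(sprintf("  k_off_short = %.4g /s, k_off_long = %.4g /s\n",
              x$k_off_short, x$k_off_long))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bootstrap standard error of a statistic
#'
#' Nonparametric bootstrap: the statistic is recomputed on `n_reps` resamples
#' (with replacement) of the input values; the SE is the standard deviation
#' of those replicates and the variance its square.
#'
#' @param samples numeric vector (length >= 2).
#' @param statistic function of a numeric vector (default [median]).
#' @param n_reps number of bootstrap replicates (default 1000, >= 2).
#' @param seed optional integer seed; the global RNG state is restored.
#' @return List with `se`, `variance`, and `n_reps`.
#' @export
bootstrap_se <- function(samples, statistic = median, n_reps = 1000L,
                         seed = NULL) {
  if (length(samples) == 0) stop("empty input")
  if (length(samples) < 2) stop("need at least 2 samples")
  if (n_reps < 2) stop("n_reps must be at least 2")
  reps <- with_seed(seed, {
    n <- length(samples)
    idx <- matrix(sample.int(n, n * n_reps, replace = TRUE), nrow = n)
    apply(idx, 2, function(ii) statistic(samples[ii]))
  })
  se <- sd(reps)
  list(se = se, variance = se^2, n_reps = as.integer(n_reps))
}
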