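#' FCS model parameters: diffusion plus two binding populations
#'
#' Parameter set of the autocorrelation model used throughout the package:
#' a freely diffusing population (fraction `f_D`, characteristic diffusion
#' time `tau_D`) and two populations bound to immobile chromatin sites with
#' short and long residence times (`f_short`/`tau_short`,
#' `f_long`/`tau_long`). `N` is the mean number of fluorescent molecules in
#' the confocal volume and `omega` the axial-to-radial waist ratio of the
#' observation volume. Fractions live on the simplex
#' `f_D + f_short + f_long = 1`.
#'
#' @param N mean number of molecules in the confocal volume (> 0).
#' @param f_D,f_short,f_long population fractions in `[0, 1]`, summing to 1
#'   (tolerance 1e-8; they are renormalized to sum exactly to 1).
#' @param tau_D characteristic diffusion time (s, > 0).
#' @param omega axial/radial waist ratio (> 0).
#' @param tau_short,tau_long residence times (s, > 0) with
#'   `tau_short < tau_long`.
#' @return An object of class `fcs_params`.
#' @examples
#' p <- fcs_params(N = 1, f_D = 0.5, f_short = 0.3, f_long = 0.2,
#'                 tau_D = 5e-4, omega = 5, tau_short = 0.02, tau_long = 2)
#' evaluate_acf_model(p, c(1e-4, 1e-2, 1))
#' @export
fcs_params <- function(N, f_D, f_short, f_long, tau_D, omega,
                       tau_short, tau_long) {
  stopifnot(is.numeric(N), length(N) == 1, N > 0,
            omega > 0, tau_D > 0, tau_short > 0, tau_long > 0)
  f <- c(f_D, f_short, f_long)
  if (any(f < -1e-12) || any(f > 1 + 1e-12))
    stop("fractions must lie in [0, 1]")
  if (abs(sum(f) - 1) > 1e-8)
    stop("fractions must sum to 1")
  f <- pmin(pmax(f, 0), 1) / sum(pmin(pmax(f, 0), 1))
  if (tau_short >= tau_long)
    stop("tau_short must be smaller than tau_long")
  structure(list(N = N, f_D = f[1], f_short = f[2], f_long = f[3],
                 tau_D = tau_D, omega = omega,
                 tau_short = tau_short, tau_long = tau_long),
            class = "fcs_params")
}

#' @export
print.fcs_params <- function(x, ...) {
  cat("FCS model parameters\n")
  cat(sprintf("  N = %.4g, omega = %.3g\n", x$N, x$omega))
  cat(sprintf("  f_D = %.3f (tau_D = %.3g s)\n", x$f_D, x$tau_D))
  cat(sprintf("  f_short = %.3f (tau_short = %.3g s)\n", x$f_short, x$tau_short))
  cat(sprintf("  f_long = %.3f (tau_long = %.3g s)\n", x$f_long, x$tau_long))
  invisible(x)
}

#' Evaluate the diffusion + two-binding-population autocorrelation model
#'
#' Computes
#' \deqn{G(\tau) = \frac{1}{2^{3/2} N}\left[f_D\left(1 +
#'   \frac{\tau}{\tau_D}\right)^{-1}\left(1 +
#'   \frac{\tau}{\omega^2\tau_D}\right)^{-1/2} +
#'   f_{short} e^{-\tau/\tau_{short}} + f_{long} e^{-\tau/\tau_{long}}\right]}
#' the amplitude-normalized fluctuation autocorrelation of a 3D Gaussian
#' observation volume crossed by diffusing molecules that also bind two
#' classes of immobile sites with exponential residence times.
#'
#' @param params an [fcs_params] object.
#' @param lags lag times (s, >= 0).
#' @return Numeric vector of G values, strictly positive and non-increasing
#'   in the lag.
#' @export
evaluate_acf_model <- function(params, lags) {
  stopifnot(inherits(params, "fcs_params"), is.numeric(lags), all(lags >= 0))
  p <- params
  diff_term <- p$f_D / ((1 + lags / p$tau_D) *
                          sqrt(1 + lags / (p$omega^2 * p$tau_D)))
  bind_term <- p$f_short * exp(-lags / p$tau_short) +
    p$f_long * exp(-lags / p$tau_long)
  (diff_term + bind_term) / (2^(3 / 2) * p$N)
}
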