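#' Binned photon-count trace from one FCS acquisition
#'
#' @param counts non-negative integer photon counts per time bin (length >= 2).
#' @param bin_width bin width in seconds (> 0).
#' @param label,cell_id,condition optional acquisition metadata.
#' @return An object of class `intensity_trace`.
#' @export
intensity_trace <- function(counts, bin_width, label = NA_character_,
                            cell_id = NA_character_, condition = NA_character_) {
  stopifnot(length(counts) >= 2, bin_width > 0)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  structure(list(counts = as.integer(round(counts)), bin_width = bin_width,
                 label = label, cell_id = cell_id, condition = condition),
            class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("Intensity trace: %d bins x %.3g s (%.3g s), mean rate %.4g counts/s\n",
              length(x$counts), x$bin_width, length(x$counts) * x$bin_width,
              mean(x$counts) / x$bin_width))
  invisible(x)
}

#' Autocorrelation curve container
#'
#' @param lags lag times in seconds, strictly increasing and positive.
#' @param G autocorrelation values (finite).
#' @param sd optional per-lag standard deviation (>= 0).
#' @param n_traces_averaged number of traces the curve averages (default 1).
#' @param duration optional acquisition duration (s); used by the fitter's
#'   default lag-range trimming.
#' @return An object of class `correlation_curve`.
#' @export
correlation_curve <- function(lags, G, sd = NULL, n_traces_averaged = 1L,
                              duration = NA_real_) {
  stopifnot(length(lags) == length(G), all(lags > 0),
            all(diff(lags) > 0), all(is.finite(G)))
  if (!is.null(sd)) stopifnot(length(sd) == length(G), all(sd >= 0))
  structure(list(lags = as.numeric(lags), G = as.numeric(G), sd = sd,
                 n_traces_averaged = as.integer(n_traces_averaged),
                 duration = duration),
            class = "correlation_curve")
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf("Correlation curve: %d lags in [%.3g, %.3g] s, G(first lag) = %.4g, n = %d\n",
              length(x$lags), min(x$lags), max(x$lags), x$G[1],
              x$n_traces_averaged))
  invisible(x)
}

#' Multi-tau lag layout
#'
#' Integer-bin lags laid out as in a multi-tau correlator: `m` linearly
#' spaced lags in the first stage, then per stage the spacing is multiplied
#' by `ratio` while the lag range doubles, yielding quasi-log coverage.
#'
#' @param max_lag largest lag, in bins.
#' @param m channels per stage (default 16).
#' @param ratio spacing multiplier between stages (default 2).
#' @return Increasing integer vector of lags (bins), bounded by `max_lag`.
#' @export
multi_tau_lags <- function(max_lag, m = 16L, ratio = 2L) {
  stopifnot(max_lag >= 1, m >= 2, ratio >= 2)
  lags <- seq_len(min(m, max_lag))
  step <- 1L
  top <- m
  while (top < max_lag) {
    step <- step * ratio
    nxt <- seq(top + step, min(top * ratio, max_lag), by = step)
    lags <- c(lags, nxt)
    top <- top * ratio
  }
  as.integer(unique(lags[lags <= max_lag]))
}

#' Autocorrelate a photon-count trace
#'
#' Estimates the normalized fluctuation autocorrelation
#' `G(tau) = <dF(t) dF(t+tau)> / <F>^2` with the symmetric (lag-matched
#' mean) normalization that corrects finite-trace bias:
#' `G(k) = sum(F_i F_{i+k}) / ((n-k) m1 m2) - 1`, where `m1`, `m2` are the
#' means of the leading and trailing lag-matched segments. Only `tau > 0` is
#' reported; the zero-lag channel is dominated by shot noise and excluded.
#'
#' The `multi_tau` scheme evaluates this estimator on a quasi-logarithmic
#' multi-tau lag grid ([multi_tau_lags]); `direct` evaluates it at every
#' integer lag up to `max_lag`. Both schemes compute the identical estimator
#' at each lag, so they agree to machine precision on shared lags.
#'
#' @param trace an [intensity_trace].
#' @param scheme `"multi_tau"` (default) or `"direct"`.
#' @param m,ratio multi-tau layout parameters (see [multi_tau_lags]).
#' @param max_lag largest lag in bins; default `length(counts) %/% 4`.
#' @return A [correlation_curve] with lags in seconds.
#' @export
autocorrelate <- function(trace, scheme = c("multi_tau", "direct"),
                          m = 16L, ratio = 2L, max_lag = NULL) {
  stopifnot(inherits(trace, "intensity_trace"))
  scheme <- match.arg(scheme)
  x <- as.numeric(trace$counts)
  n <- length(x)
  if (mean(x) <= 0) stop("degenerate trace: zero mean, normalization undefined")
  if (var(x) == 0) stop("degenerate trace: zero variance")
  if (is.null(max_lag)) max_lag <- n %/% 4L
  max_lag <- min(max_lag, n - 2L)
  lags <- if (scheme == "multi_tau") multi_tau_lags(max_lag, m, ratio)
          else seq_len(max_lag)
  g <- autocorr_lags_cpp(x, as.integer(lags))
  ok <- is.finite(g)
  correlation_curve(lags[ok] * trace$bin_width, g[ok],
                    duration = n * trace$bin_width)
}

#' Average correlation curves sharing a lag grid
#'
#' Per-lag mean and standard deviation over curves measured in different
#' cells. For display, `normalize = TRUE` divides the mean curve by the mean
#' G over the first `k` lags (fits always use unnormalized curves).
#'
#' @param curves list of [correlation_curve] objects on an identical lag grid.
#' @param normalize divide by the mean of the first `k` lags (default FALSE).
#' @param k number of leading lags defining the normalization amplitude.
#' @return A [correlation_curve] with per-lag `sd` and
#'   `n_traces_averaged = length(curves)`.
#' @export
average_curves <- function(curves, normalize = FALSE, k = 3L) {
  if (length(curves) == 0) stop("empty curve list")
  stopifnot(all(vapply(curves, inherits, TRUE, "correlation_curve")))
  lags <- curves[[1]]$lags
  for (cv in curves)
    if (length(cv$lags) != length(lags) || any(cv$lags != lags))
      stop("curves do not share an identical lag grid")
  gm <- do.call(rbind, lapply(curves, `[[`, "G"))
  mu <- colMeans(gm)
  sdv <- if (nrow(gm) > 1) apply(gm, 2, sd) else rep(0, ncol(gm))
  if (normalize) {
    amp <- mean(mu[seq_len(min(k, length(mu)))])
    mu <- mu / amp
    sdv <- sdv / abs(amp)
  }
  dur <- suppressWarnings(mean(vapply(curves, function(cv)
    if (is.null(cv$duration)) NA_real_ else cv$duration, 0), na.rm = TRUE))
  out <- correlation_curve(lags, mu, sd = sdv,
                           n_traces_averaged = length(curves),
                           duration = if (is.finite(dur)) dur else NA_real_)
  out
}
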