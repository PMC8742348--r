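#' Write / read a photon-count trace as two-column CSV
#'
#' Columns `time_s` (bin start) and `counts`. The bin width is recovered from
#' the time column on read.
#'
#' @param trace an [intensity_trace].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "intensity_trace"))
  df <- data.frame(time_s = (seq_along(trace$counts) - 1) * trace$bin_width,
                   counts = trace$counts)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("time_s", "counts") %in% names(df)), nrow(df) >= 2)
  intensity_trace(df$counts, bin_width = df$time_s[2] - df$time_s[1])
}

#' Write / read a correlation curve as CSV
#'
#' Columns `lag_s`, `G`, `sd`, `n`.
#'
#' @param curve a [correlation_curve].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "correlation_curve"))
  df <- data.frame(lag_s = curve$lags, G = curve$G,
                   sd = if (is.null(curve$sd)) NA_real_ else curve$sd,
                   n = curve$n_traces_averaged)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  df <- read.csv(path)
  correlation_curve(df$lag_s, df$G,
                    sd = if (all(is.na(df$sd))) NULL else df$sd,
                    n_traces_averaged = df$n[1])
}

#' Write / read a nucleus stack as multi-page TIFF with a JSON sidecar
#'
#' One TIFF page per z-slice, 16-bit, intensities scaled to `[0, 1]`; the
#' sidecar (`<path>.json`) stores the voxel sizes, dimensions, and intensity
#' scale so counts are restored on read (up to 16-bit quantization).
#'
#' @param image a [nucleus_image].
#' @param path TIFF path.
#' @return `path`, invisibly.
#' @export
write_nucleus_tiff <- function(image, path) {
  stopifnot(inherits(image, "nucleus_image"))
  x <- image$data
  scale <- max(x, 1e-12)
  pages <- lapply(seq_len(dim(x)[3]), function(k) x[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  sidecar <- list(voxel_size_um = image$voxel_size, dim = dim(x),
                  intensity_scale = scale, channel = image$channel)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_nucleus_tiff
#' @export
read_nucleus_tiff <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  x <- array(0, dim = sidecar$dim)
  for (k in seq_along(pages)) x[, , k] <- pages[[k]] * sidecar$intensity_scale
  ch <- sidecar$channel
  nucleus_image(x, sidecar$voxel_size_um,
                channel = if (is.null(ch)) NA_character_ else ch)
}
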