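#' Otsu threshold of an intensity sample
#'
#' Maximizes between-class variance over a 256-bin histogram.
#'
#' @param x numeric vector or array of intensities.
#' @param n_bins histogram resolution (default 256).
#' @return Threshold value on the intensity scale.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) == 0) stop("constant image: threshold undefined")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  bcv <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- 0
  mids[which.max(bcv)]
}

#' Segment nuclei in a denoised stack
#'
#' Global automatic threshold (Otsu), 26-connected component labeling,
#' slice-wise hole filling, and physical size gating: components with volume
#' outside `[min_volume, max_volume]` (um^3) are discarded. Surviving labels
#' are renumbered 1..K by decreasing volume.
#'
#' @param image a denoised [nucleus_image].
#' @param threshold_method `"otsu"` (default) or a numeric threshold.
#' @param min_volume,max_volume nucleus volume bounds in um^3
#'   (defaults 50 and 4000).
#' @return A [nucleus_mask].
#' @export
segment_nuclei <- function(image, threshold_method = "otsu",
                           min_volume = 50, max_volume = 4000) {
  stopifnot(inherits(image, "nucleus_image"), min_volume >= 0,
            max_volume > min_volume)
  x <- image$data
  d <- dim(x)
  thr <- if (is.numeric(threshold_method)) threshold_method
         else switch(match.arg(threshold_method, "otsu"), otsu = otsu_threshold(x))
  fg <- x > thr
  if (!any(fg)) stop("no nuclei found")
  lab <- array(label_components26_cpp(as.vector(fg), d), d)
  vvol <- prod(image$voxel_size)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes * vvol >= min_volume & sizes * vvol <= max_volume)
  if (length(keep) == 0) stop("no nuclei found")
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  out <- array(0L, d)
  for (i in seq_along(keep)) {
    bin <- lab == keep[i]
    bin <- array(fill_holes_slices_cpp(as.vector(bin), d), d)
    out[bin & out == 0L] <- i
  }
  nucleus_mask(out, image$voxel_size)
}
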