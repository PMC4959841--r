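# Per-section intensity normalization and clustering-based global thresholding.
#
# DAB-labeled (electron-dense) structures are DARK: the foreground of every
# binary mask produced here is the low-intensity, closed set {v <= tau'}.

#' Thresholding parameters
#'
#' Parameters of the clustering-based (Otsu) global threshold and its
#' marker-specific modulation. The modulation shrinks the data-driven
#' threshold toward the known contrast-enhanced intensity range of the
#' peroxidase/DAB label: thresholds below `cutoff` are scaled by
#' `factor_low`, all others by `factor_high` (the comparison is strict, so a
#' threshold exactly at `cutoff` uses `factor_high`). Both factors are at
#' most 1, so modulation only tightens the dark-foreground criterion.
#'
#' @param cutoff Intensity on (0, 1) separating the two modulation branches.
#' @param factor_low,factor_high Multiplicative factors on (0, 1] applied
#'   below / at-or-above `cutoff`.
#' @param n_bins Number of histogram bins over \[0, 1\] used for equalization
#'   and threshold search.
#' @return A `threshold_params` list.
#' @export
#' @examples
#' threshold_params()
threshold_params <- function(cutoff = 0.6, factor_low = 0.82,
                             factor_high = 0.86, n_bins = 256L) {
  check_scalar(cutoff, "cutoff", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  check_scalar(factor_low, "factor_low", 0, 1, strict_lower = TRUE)
  check_scalar(factor_high, "factor_high", 0, 1, strict_lower = TRUE)
  check_scalar(n_bins, "n_bins", 2)
  structure(list(cutoff = cutoff, factor_low = factor_low,
                 factor_high = factor_high, n_bins = as.integer(n_bins)),
            class = "threshold_params")
}

#' Histogram equalization of a grayscale section
#'
#' Maps intensities through the image's own cumulative histogram so that
#' sections acquired with different brightness/contrast settings become
#' comparable. The mapping is a monotone non-decreasing function of input
#' intensity; a constant image maps to a constant image.
#'
#' @param img Numeric matrix with intensities in \[0, 1\].
#' @param n_bins Number of histogram bins.
#' @return A matrix of the same shape with intensities in \[0, 1\].
#' @export
equalize_histogram <- function(img, n_bins = 256L) {
  check_image(img)
  check_scalar(n_bins, "n_bins", 2)
  n_bins <- as.integer(n_bins)
  bins <- intensity_bin(img, n_bins)
  counts <- tabulate(bins, nbins = n_bins)
  cdf <- cumsum(counts) / length(img)
  out <- img
  out[] <- cdf[bins]
  out
}

#' Clustering-based global threshold (Otsu criterion)
#'
#' Computes the global threshold that best separates an image into two
#' intensity classes by exhaustively maximizing the between-class variance
#' over `n_bins` candidate bin edges (Otsu's criterion). Ties break toward
#' the lowest threshold, which gives the smaller (more conservative) dark
#' foreground.
#'
#' @param img Numeric matrix with intensities in \[0, 1\].
#' @param params A [threshold_params()] object (supplies `n_bins`).
#' @return The threshold as a bin edge in (0, 1): pixels with intensity
#'   strictly below it form the lower class.
#' @export
cluster_threshold <- function(img, params = threshold_params()) {
  check_image(img)
  stopifnot(inherits(params, "threshold_params"))
  n_bins <- params$n_bins
  counts <- tabulate(intensity_bin(img, n_bins), nbins = n_bins)
  if (sum(counts > 0L) < 2L) {
    abort("degenerate histogram: image has fewer than 2 occupied intensity bins")
  }
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  w <- counts / sum(counts)
  # cumulative class probability and mean for thresholds after bin k
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_total <- mu[n_bins]
  k <- seq_len(n_bins - 1L)
  valid <- omega[k] > 0 & omega[k] < 1
  sigma_b <- rep(-Inf, n_bins - 1L)
  sigma_b[valid] <- (mu_total * omega[k][valid] - mu[k][valid])^2 /
    (omega[k][valid] * (1 - omega[k][valid]))
  best <- which.max(sigma_b)  # first maximum = lowest threshold on ties
  best / n_bins
}

#' Modulate a global threshold toward the marker's intensity range
#'
#' Applies the fixed piecewise rule tuned to contrast-enhanced DAB labels:
#' `tau * factor_low` when `tau < cutoff` (strict), else `tau * factor_high`.
#' With the defaults: 0.50 -> 0.41 and 0.70 -> 0.602.
#'
#' @param tau Threshold in \[0, 1\].
#' @param params A [threshold_params()] object.
#' @return The modulated threshold, always `<= tau`.
#' @export
modulate_threshold <- function(tau, params = threshold_params()) {
  check_scalar(tau, "tau", 0, 1)
  stopifnot(inherits(params, "threshold_params"))
  if (tau < params$cutoff) tau * params$factor_low else tau * params$factor_high
}

#' Binarize a section into a dark-foreground mask
#'
#' Foreground pixels are those with intensity at or below the threshold
#' (closed lower set): the electron-dense label is dark, so the foreground
#' criterion selects low intensities.
#'
#' @param img Numeric matrix with intensities in \[0, 1\].
#' @param tau_prime Threshold in \[0, 1\].
#' @return Logical matrix of the same shape (`TRUE` = foreground).
#' @export
binarize <- function(img, tau_prime) {
  check_image(img)
  check_scalar(tau_prime, "tau_prime", 0, 1)
  img <= tau_prime
}

#' Contrast-to-noise ratio between two pixel classes
#'
#' `CNR = (mu2 - mu1) / sqrt(sd2^2 + sd1^2)` computed over the two pixel
#' sets. Positive when class 2 is brighter than class 1; swapping the
#' classes negates the result. If both spreads are zero the result is 0 for
#' equal means and signed infinity otherwise.
#'
#' @param class1,class2 Numeric vectors of pixel intensities.
#' @return A scalar CNR value.
#' @export
#' @examples
#' cnr(rnorm(1e4, 100, 10), rnorm(1e4, 150, 10))  # ~ 3.54
cnr <- function(class1, class2) {
  if (length(class1) == 0L || length(class2) == 0L) {
    abort("both pixel classes must be nonempty")
  }
  d <- mean(class2) - mean(class1)
  s1 <- if (length(class1) > 1L) sd(class1) else 0
  s2 <- if (length(class2) > 1L) sd(class2) else 0
  denom <- sqrt(s1^2 + s2^2)
  if (denom == 0) {
    if (d == 0) 0 else sign(d) * Inf
  } else {
    d / denom
  }
}
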