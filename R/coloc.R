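# Pixel-level colocalization: Gaussian preprocessing, thresholding, the
# intensity correlation quotient (ICQ), percent pixel overlap referenced to
# a channel, and triple-mask conjunction.

# Discretized, renormalized Gaussian kernel (radius 4 sigma).
gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# 1D convolution along the first margin of a matrix with reflective
# boundary handling; x is (n, m), k has odd length.
conv_cols_reflect <- function(x, k) {
  n <- nrow(x)
  r <- (length(k) - 1L) / 2L
  # reflect indices about the edges (1-based mirror without repeating edge)
  idx <- c(rev(seq_len(r) + 1L), seq_len(n), n - seq_len(r))
  idx[idx < 1L] <- 1L
  idx[idx > n] <- n
  xp <- x[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(x))
  for (j in seq_along(k)) {
    out <- out + k[j] * xp[(j - 1L) + seq_len(n), , drop = FALSE]
  }
  out
}

# Separable convolution along one axis of a 3D array.
conv_axis <- function(arr, k, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(arr, perm)
  m <- matrix(x, nrow = d[axis])
  m <- conv_cols_reflect(m, k)
  x <- array(m, d[perm])
  aperm(x, order(perm))
}

#' Gaussian smoothing of an image or stack
#'
#' Separable Gaussian convolution with reflective boundaries, applied as a
#' true 3D filter to volumes (all three axes) and as a 2D filter to
#' matrices. `sigma = 0` returns the input unchanged. This is the standard
#' preprocessing step (sigma 1) applied before colocalization and object
#' analysis to suppress shot noise and ease object detection.
#'
#' @param x A 2D matrix (y, x) or 3D array (z, y, x).
#' @param sigma Gaussian sigma in pixels/voxels; must be >= 0.
#' @return Smoothed copy of `x`, same dimensions.
#' @export
gaussian_preprocess <- function(x, sigma = 1) {
  stop_if_not(sigma >= 0, "sigma must be >= 0")
  if (sigma == 0) return(x)
  k <- gaussian_kernel_1d(sigma)
  if (is.matrix(x)) {
    out <- conv_cols_reflect(x, k)
    out <- t(conv_cols_reflect(t(out), k))
    return(out)
  }
  stop_if_not(length(dim(x)) == 3, "x must be a matrix or a 3D array")
  for (ax in 1:3) x <- conv_axis(x, k, ax)
  x
}

#' Threshold a channel into a foreground mask
#'
#' Default thresholding is Otsu's method (between-class variance
#' maximization on a 256-bin histogram, via \pkg{EBImage}), computed over
#' the whole volume; manual thresholds are supported where an absolute
#' cutoff is known. Acquisition-time LUT thresholds are not reproducible
#' post hoc, so Otsu is the default analysis choice.
#'
#' @param x Intensity matrix or 3D array.
#' @param method `"otsu"` or a single numeric manual threshold.
#' @return A logical mask (`x > threshold`) with attribute `"threshold"`.
#' @export
threshold_channel <- function(x, method = "otsu") {
  stop_if_not(length(x) > 0, "empty input")
  if (is.numeric(method)) {
    thr <- method
  } else if (identical(method, "otsu")) {
    rng <- range(x)
    if (diff(rng) == 0) {
      stop("no separable classes: constant image", call. = FALSE)
    }
    thr <- EBImage::otsu(matrix(as.numeric(x), ncol = 1),
                         range = rng, levels = 256L)
  } else {
    stop("unknown thresholding method: ", method, call. = FALSE)
  }
  mask <- x > thr
  attr(mask, "threshold") <- as.numeric(thr)
  mask
}

#' Intensity correlation quotient (ICQ)
#'
#' Sign-based covariation statistic: over the analysis domain, the
#' fraction of voxels whose deviation product
#' \eqn{(A_i - \bar A)(B_i - \bar B)} is positive, among voxels with a
#' nonzero product, minus 0.5. Ranges over \[-0.5, 0.5\]; +0.5 for
#' perfectly covarying channels, -0.5 for perfectly anti-varying ones,
#' near 0 for independent channels. `2 * ICQ` below 0.1 in absolute value
#' is conventionally treated as chance-level colocalization.
#'
#' The analysis domain is `roi` when supplied, otherwise the whole image.
#' When colocalization is "referenced" to a channel, pass that channel's
#' foreground mask as `roi` (see [coloc_pair()]). Means are computed over
#' the same domain. Voxels with an exactly zero deviation product carry no
#' covariation information and are excluded by default
#' (`zero_policy = "exclude"`); `zero_policy = "negative"` counts them as
#' non-positive.
#'
#' @param a,b Aligned intensity arrays of identical shape.
#' @param roi Optional logical array: the analysis domain.
#' @param zero_policy `"exclude"` or `"negative"`.
#' @return A list: `icq`, `two_icq`, `n_pixels_used`.
#' @export
icq <- function(a, b, roi = NULL, zero_policy = c("exclude", "negative")) {
  zero_policy <- match.arg(zero_policy)
  stop_if_not(identical(dim(a), dim(b)), "channel shapes differ")
  if (is.null(roi)) roi <- rep(TRUE, length(a))
  stop_if_not(length(roi) == length(a), "roi shape differs from channels")
  av <- as.numeric(a)[as.logical(roi)]
  bv <- as.numeric(b)[as.logical(roi)]
  stop_if_not(length(av) >= 2, "analysis domain has fewer than 2 voxels")
  if (diff(range(av)) == 0 || diff(range(bv)) == 0) {
    stop("undefined covariation: constant channel in analysis domain",
         call. = FALSE)
  }
  prod <- (av - mean(av)) * (bv - mean(bv))
  if (zero_policy == "exclude") {
    used <- prod != 0
  } else {
    used <- rep(TRUE, length(prod))
  }
  n_used <- sum(used)
  stop_if_not(n_used > 0, "undefined covariation: all products are zero")
  q <- sum(prod[used] > 0) / n_used - 0.5
  list(icq = q, two_icq = 2 * q, n_pixels_used = n_used)
}

#' Percent pixel overlap referenced to a channel
#'
#' Of the reference-channel foreground voxels, the percentage also in the
#' other channel's foreground: `100 * |ref & other| / |ref|`. A spatial
#' (intensity-independent) colocalization measure.
#'
#' @param mask_ref Reference logical mask (must be non-empty).
#' @param mask_other Other channel's logical mask, same shape.
#' @return Percent in \[0, 100\].
#' @export
overlap_pct <- function(mask_ref, mask_other) {
  stop_if_not(identical(dim(mask_ref), dim(mask_other)),
              "mask shapes differ")
  n_ref <- sum(mask_ref)
  if (n_ref == 0) stop("reference domain empty", call. = FALSE)
  100 * sum(mask_ref & mask_other) / n_ref
}

#' Voxelwise conjunction of three masks
#'
#' Triple-colocalization domain: voxels positive in all three channels
#' (the mask-calculator AND used before object counting in
#' triple-labeling experiments).
#'
#' @param mask_a,mask_b,mask_c Logical arrays of identical shape.
#' @return Logical array.
#' @export
triple_mask <- function(mask_a, mask_b, mask_c) {
  stop_if_not(identical(dim(mask_a), dim(mask_b)) &&
                identical(dim(mask_a), dim(mask_c)),
              "mask shapes differ")
  mask_a & mask_b & mask_c
}

#' Full pixel-colocalization analysis of a channel pair
#'
#' The standard per-cell workflow: Gaussian preprocessing of both
#' channels, per-channel thresholding, then ICQ and percent pixel overlap
#' referenced to channel A (both computed over the A-positive domain,
#' intersected with `roi_mask` when given).
#'
#' @param stack_a Reference channel (e.g. the immunolabeled protein).
#' @param stack_b Marker channel.
#' @param roi_mask Optional logical array restricting the analysis domain.
#' @param sigma Preprocessing Gaussian sigma (default 1).
#' @param method Thresholding method passed to [threshold_channel()].
#' @param zero_policy Passed to [icq()].
#' @return A one-row data.frame: `icq`, `two_icq`, `overlap_pct_ref_a`,
#'   `threshold_a`, `threshold_b`, `n_pixels_used`.
#' @export
coloc_pair <- function(stack_a, stack_b, roi_mask = NULL, sigma = 1,
                       method = "otsu", zero_policy = "exclude") {
  a <- gaussian_preprocess(stack_a, sigma)
  b <- gaussian_preprocess(stack_b, sigma)
  mask_a <- threshold_channel(a, method)
  mask_b <- threshold_channel(b, method)
  domain <- mask_a
  if (!is.null(roi_mask)) domain <- domain & roi_mask
  res <- icq(a, b, roi = domain, zero_policy = zero_policy)
  ref <- mask_a
  if (!is.null(roi_mask)) ref <- ref & roi_mask
  ov <- overlap_pct(ref, mask_b)
  data.frame(icq = res$icq, two_icq = res$two_icq,
             overlap_pct_ref_a = ov,
             threshold_a = attr(mask_a, "threshold"),
             threshold_b = attr(mask_b, "threshold"),
             n_pixels_used = res$n_pixels_used)
}
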