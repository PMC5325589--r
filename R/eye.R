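# Ommatidial-lattice quantification: local-maxima detection, nearest-
# neighbor distances, a lattice regularity index, and percent recovery.

#' Detect local intensity maxima in a 2D image
#'
#' A pixel is a candidate maximum if it is at least as bright as every
#' pixel in its `(2 min_distance + 1)^2` neighborhood and brighter than
#' `rel_threshold * max(image)`. Candidates are then accepted greedily in
#' decreasing intensity order (ties broken in row-major order, making the
#' result deterministic), discarding any candidate within `min_distance`
#' of an accepted one.
#'
#' @param image 2D intensity matrix (y, x).
#' @param min_distance Minimum separation between reported maxima (pixels).
#' @param rel_threshold Intensity threshold relative to the image maximum,
#'   in \[0, 1\].
#' @return data.frame of maxima: `x`, `y` (1-based pixel coordinates),
#'   `intensity`; may be empty.
#' @export
detect_maxima <- function(image, min_distance = 5, rel_threshold = 0.2) {
  stop_if_not(is.matrix(image), "image must be a 2D matrix")
  h <- nrow(image); w <- ncol(image)
  r <- max(1L, ceiling(min_distance))
  thr <- rel_threshold * max(image)
  cand <- which(image > thr)
  if (length(cand) == 0) {
    return(data.frame(x = numeric(0), y = numeric(0), intensity = numeric(0)))
  }
  cy <- ((cand - 1L) %% h) + 1L
  cx <- ((cand - 1L) %/% h) + 1L
  is_max <- vapply(seq_along(cand), function(i) {
    ys <- max(1L, cy[i] - r):min(h, cy[i] + r)
    xs <- max(1L, cx[i] - r):min(w, cx[i] + r)
    image[cy[i], cx[i]] >= max(image[ys, xs])
  }, logical(1))
  cy <- cy[is_max]; cx <- cx[is_max]
  val <- image[cbind(cy, cx)]
  ord <- order(-val, cy, cx)
  cy <- cy[ord]; cx <- cx[ord]; val <- val[ord]
  keep <- logical(length(val))
  for (i in seq_along(val)) {
    if (i == 1 || all((cy[keep] - cy[i])^2 + (cx[keep] - cx[i])^2 >=
                        min_distance^2)) {
      keep[i] <- TRUE
    }
  }
  out <- data.frame(x = cx[keep], y = cy[keep], intensity = val[keep])
  out[order(out$y, out$x), , drop = FALSE]
}

#' Nearest-neighbor distances among point coordinates
#'
#' Euclidean distance from each point to its nearest other point.
#'
#' @param coords data.frame or matrix with columns `x`, `y` (at least 2
#'   points).
#' @return Numeric vector of distances, one per point.
#' @export
nn_distances <- function(coords) {
  coords <- as.data.frame(coords)
  n <- nrow(coords)
  stop_if_not(n >= 2, "need at least 2 points")
  d <- as.matrix(stats::dist(coords[, c("x", "y")]))
  diag(d) <- Inf
  apply(d, 1, min)
}

#' Ommatidial lattice regularity index (IREG)
#'
#' A composite regularity index responding to the two signatures of
#' photoreceptor degeneration: ommatidial loss (fewer detected lattice
#' spots) and lattice disorder (dispersed nearest-neighbor distances).
#' Defined here as
#' \deqn{IREG = \frac{n_{spots}}{1 + CV}}
#' where CV is the coefficient of variation of the nearest-neighbor
#' distances. A perfect lattice of n spots scores n; jitter or dropout
#' reduce the score. The published index this emulates is defined in
#' external software; this composite is this package's own documented
#' stand-in and is validated by its properties (monotonicity under
#' disorder, invariance under rigid motion), not by value matching.
#'
#' @param coords Spot coordinates (columns `x`, `y`), >= 2 points.
#' @param normalize_to Optional reference IREG (e.g. the control
#'   genotype's); when given the result is divided by it.
#' @return IREG (dimensionless, > 0).
#' @export
iregularity <- function(coords, normalize_to = NULL) {
  d <- nn_distances(coords)
  m <- mean(d)
  if (m == 0) stop("all nearest-neighbor distances are zero", call. = FALSE)
  cv <- stats::sd(d) / m
  ireg <- nrow(as.data.frame(coords)) / (1 + cv)
  if (!is.null(normalize_to)) ireg <- ireg / normalize_to
  ireg
}

#' Percent recovery of eye regularity
#'
#' Affine rescaling of a regularity score onto a 0--100 scale anchored at
#' the average degenerated eye (0%) and the control wild-type eye (100%).
#'
#' @param ireg_x Score to map.
#' @param ireg_degenerated Average degenerated-eye score (the 0% anchor).
#' @param ireg_control Control-eye score (the 100% anchor).
#' @return Percent recovery (may exceed \[0, 100\] for scores outside the
#'   anchors).
#' @export
percent_recovery <- function(ireg_x, ireg_degenerated, ireg_control) {
  if (ireg_control == ireg_degenerated) {
    stop("degenerate anchors: control equals degenerated", call. = FALSE)
  }
  100 * (ireg_x - ireg_degenerated) / (ireg_control - ireg_degenerated)
}
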