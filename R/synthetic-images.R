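# Synthetic image generators: vesicle-bearing two-channel stacks with
# controlled colocalization, jittered hexagonal spot lattices, and random
# particle fields. All coordinates follow R's native 1-based indexing and
# arrays are ordered (z, y, x); 2D images are (y, x) matrices.

#' Specification of a two-channel synthetic vesicle scene
#'
#' Describes a pair of aligned 3D stacks populated with PSF-blurred
#' point-like vesicles. A controlled fraction of channel-A vesicles share
#' their position with a channel-B vesicle, and peak intensities at shared
#' positions covary with a configurable correlation. Default voxel size
#' (0.3777 x 0.06 x 0.06 micrometers, z/y/x) matches high-zoom confocal
#' acquisition of cultured cells.
#'
#' @param shape Stack dimensions in voxels, `c(z, y, x)`.
#' @param voxel_size Voxel edge lengths in micrometers, `c(z, y, x)`.
#' @param n_vesicles_a,n_vesicles_b Vesicle counts per channel.
#' @param coloc_fraction Fraction in \[0, 1\] of channel-A vesicles placed
#'   at a shared position with a channel-B vesicle.
#' @param intensity_rho Correlation in \[-1, 1\] of peak intensities at
#'   shared positions.
#' @param psf_sigma Gaussian blob sigma in voxels (point-spread stand-in).
#' @param noise_sd Additive Gaussian noise sd (a.u.).
#' @param membrane_ring If `TRUE`, adds a plasma-membrane-like shell of
#'   channel-A signal around the cell midplane.
#' @param peak_intensity Mean vesicle peak intensity (a.u.).
#' @param min_separation Minimum center-to-center distance (voxels)
#'   enforced between distinct vesicle positions.
#' @param seed Integer RNG seed.
#' @return An object of class `"vesicle_scene_spec"`.
#' @export
vesicle_scene_spec <- function(shape = c(16, 64, 64),
                               voxel_size = c(0.3777, 0.06, 0.06),
                               n_vesicles_a = 30, n_vesicles_b = 30,
                               coloc_fraction = 0.5, intensity_rho = 0.5,
                               psf_sigma = 1.5, noise_sd = 1,
                               membrane_ring = FALSE,
                               peak_intensity = 100,
                               min_separation = 8, seed = 1) {
  stop_if_not(coloc_fraction >= 0 && coloc_fraction <= 1,
              "coloc_fraction must lie in [0, 1]")
  stop_if_not(intensity_rho >= -1 && intensity_rho <= 1,
              "intensity_rho must lie in [-1, 1]")
  stop_if_not(n_vesicles_a >= 0 && n_vesicles_b >= 0,
              "vesicle counts must be >= 0")
  stop_if_not(noise_sd >= 0, "noise_sd must be >= 0")
  stop_if_not(length(shape) == 3, "shape must be c(z, y, x)")
  structure(as.list(environment()), class = "vesicle_scene_spec")
}

# Add an isotropic Gaussian blob of given peak amplitude at a (possibly
# fractional) center, truncated at 4 sigma. arr is (z, y, x).
add_blob <- function(arr, center, sigma, amplitude) {
  d <- dim(arr)
  r <- ceiling(4 * sigma)
  rng <- lapply(1:3, function(k) {
    max(1, floor(center[k] - r)):min(d[k], ceiling(center[k] + r))
  })
  gz <- exp(-(rng[[1]] - center[1])^2 / (2 * sigma^2))
  gy <- exp(-(rng[[2]] - center[2])^2 / (2 * sigma^2))
  gx <- exp(-(rng[[3]] - center[3])^2 / (2 * sigma^2))
  blob <- amplitude * (gz %o% gy %o% gx)
  arr[rng[[1]], rng[[2]], rng[[3]]] <-
    arr[rng[[1]], rng[[2]], rng[[3]], drop = FALSE] + blob
  arr
}

# Rejection-sample n points inside margins with pairwise min separation.
place_points <- function(n, shape, margin, min_sep, max_tries = 20000L) {
  pts <- matrix(numeric(0), ncol = 3)
  lo <- pmin(margin + 1, shape)
  hi <- shape - margin
  if (n > 0 && any(hi < lo)) {
    stop("placement failure: stack too small for the requested vesicles",
         call. = FALSE)
  }
  tries <- 0L
  while (nrow(pts) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("placement failure: could not place vesicles with the requested ",
           "separation", call. = FALSE)
    }
    p <- lo + stats::runif(3) * (hi - lo)
    if (nrow(pts) == 0 ||
        min(sqrt(colSums((t(pts) - p)^2))) >= min_sep) {
      pts <- rbind(pts, p)
    }
  }
  pts
}

#' Generate a two-channel vesicle scene with known colocalization truth
#'
#' Exactly `round(coloc_fraction * n_vesicles_a)` channel-A vesicles are
#' co-positioned with a channel-B vesicle; remaining vesicles of both
#' channels occupy distinct positions. Peak intensities are
#' `peak_intensity * (1 + 0.05 z)` with standard normal `z`, correlated
#' across channels at shared positions with correlation `intensity_rho`.
#'
#' @param spec A [vesicle_scene_spec()].
#' @return A list with `stack_a`, `stack_b` (3D arrays, (z, y, x)) and
#'   `truth`: a data.frame of vesicle positions (`channel`, `z`, `y`, `x`,
#'   `peak`, `shared`).
#' @export
make_vesicle_scene <- function(spec) {
  stopifnot(inherits(spec, "vesicle_scene_spec"))
  d <- spec$shape
  n_shared <- round(spec$coloc_fraction * spec$n_vesicles_a)
  n_total <- spec$n_vesicles_a + spec$n_vesicles_b - n_shared
  with_seed(spec$seed, {
    margin <- ceiling(2 * spec$psf_sigma)
    pts <- place_points(n_total, d, margin, spec$min_separation)
    # first n_vesicles_a rows are channel-A positions; the first n_shared of
    # those also host a channel-B vesicle; the rest of B is appended.
    a_idx <- seq_len(spec$n_vesicles_a)
    b_own <- if (spec$n_vesicles_b > n_shared) {
      spec$n_vesicles_a + seq_len(spec$n_vesicles_b - n_shared)
    } else integer(0)
    za <- stats::rnorm(spec$n_vesicles_a)
    zb_shared <- spec$intensity_rho * za[seq_len(n_shared)] +
      sqrt(1 - spec$intensity_rho^2) * stats::rnorm(n_shared)
    zb_own <- stats::rnorm(length(b_own))
    peak_a <- spec$peak_intensity * pmax(0.2, 1 + 0.05 * za)
    peak_b <- spec$peak_intensity *
      pmax(0.2, 1 + 0.05 * c(zb_shared, zb_own))
    stack_a <- array(0, d)
    stack_b <- array(0, d)
    for (i in a_idx) {
      stack_a <- add_blob(stack_a, pts[i, ], spec$psf_sigma, peak_a[i])
    }
    b_pos_idx <- c(seq_len(n_shared), b_own)
    for (j in seq_along(b_pos_idx)) {
      stack_b <- add_blob(stack_b, pts[b_pos_idx[j], ], spec$psf_sigma,
                          peak_b[j])
    }
    if (spec$membrane_ring) {
      # spherical shell of A signal centered mid-volume (plasma-membrane
      # stand-in)
      ctr <- (d + 1) / 2
      rad <- 0.45 * min(d[2], d[3])
      idx <- as.matrix(expand.grid(z = seq_len(d[1]), y = seq_len(d[2]),
                                   x = seq_len(d[3])))
      rr <- sqrt((idx[, 2] - ctr[2])^2 + (idx[, 3] - ctr[3])^2)
      shell <- 0.5 * spec$peak_intensity *
        exp(-(rr - rad)^2 / (2 * spec$psf_sigma^2))
      stack_a <- stack_a + array(shell, d)
    }
    if (spec$noise_sd > 0) {
      stack_a <- pmax(stack_a + array(stats::rnorm(prod(d), 0, spec$noise_sd), d), 0)
      stack_b <- pmax(stack_b + array(stats::rnorm(prod(d), 0, spec$noise_sd), d), 0)
    }
    truth_a <- if (spec$n_vesicles_a > 0) {
      data.frame(channel = "A", z = pts[a_idx, 1], y = pts[a_idx, 2],
                 x = pts[a_idx, 3], peak = peak_a,
                 shared = a_idx <= n_shared, stringsAsFactors = FALSE)
    } else NULL
    truth_b <- if (length(b_pos_idx) > 0) {
      data.frame(channel = "B", z = pts[b_pos_idx, 1], y = pts[b_pos_idx, 2],
                 x = pts[b_pos_idx, 3], peak = peak_b,
                 shared = seq_along(b_pos_idx) <= n_shared,
                 stringsAsFactors = FALSE)
    } else NULL
    list(stack_a = stack_a, stack_b = stack_b,
         truth = rbind(truth_a, truth_b))
  })
}

#' Specification of a jittered hexagonal spot lattice
#'
#' Emulates the external surface of a compound eye: a hexagonal array of
#' Gaussian spots (ommatidia) with positional jitter (lattice disorder)
#' and random dropout (ommatidial loss).
#'
#' @param rows,cols Lattice dimensions (spot counts).
#' @param spacing Nearest-neighbor spacing (pixels); keep above
#'   `4 * spot_sigma` so spots stay resolvable.
#' @param jitter_sd Positional jitter sd (pixels).
#' @param dropout_fraction Fraction of spots removed at random, in \[0, 1\].
#' @param spot_sigma Gaussian spot sigma (pixels).
#' @param noise_sd Additive Gaussian image noise sd (a.u.).
#' @param peak_intensity Spot peak intensity (a.u.).
#' @param seed Integer RNG seed.
#' @return An object of class `"lattice_spec"`.
#' @export
lattice_spec <- function(rows = 10, cols = 10, spacing = 12, jitter_sd = 0,
                         dropout_fraction = 0, spot_sigma = 2, noise_sd = 0,
                         peak_intensity = 100, seed = 1) {
  stop_if_not(dropout_fraction >= 0 && dropout_fraction <= 1,
              "dropout_fraction must lie in [0, 1]")
  stop_if_not(rows >= 1 && cols >= 1, "rows and cols must be >= 1")
  structure(as.list(environment()), class = "lattice_spec")
}

#' Generate a hexagonal spot-lattice image with ground-truth coordinates
#'
#' @param spec A [lattice_spec()].
#' @return A list with `image` (matrix, (y, x)) and `truth` (data.frame
#'   of surviving spot centers `x`, `y` after jitter and dropout).
#' @export
make_lattice_image <- function(spec) {
  stopifnot(inherits(spec, "lattice_spec"))
  with_seed(spec$seed, {
    ij <- expand.grid(i = seq_len(spec$rows) - 1, j = seq_len(spec$cols) - 1)
    x <- ij$j * spec$spacing + (ij$i %% 2) * spec$spacing / 2
    y <- ij$i * spec$spacing * sqrt(3) / 2
    margin <- spec$spacing
    x <- x + margin
    y <- y + margin
    if (spec$jitter_sd > 0) {
      x <- x + stats::rnorm(length(x), 0, spec$jitter_sd)
      y <- y + stats::rnorm(length(y), 0, spec$jitter_sd)
    }
    keep <- stats::runif(length(x)) >= spec$dropout_fraction
    x <- x[keep]
    y <- y[keep]
    w <- ceiling(max(spec$cols * spec$spacing, 1) + 2 * margin)
    h <- ceiling(max(spec$rows * spec$spacing * sqrt(3) / 2, 1) + 2 * margin)
    img <- array(0, c(1, h, w))
    for (k in seq_along(x)) {
      img <- add_blob(img, c(1, y[k], x[k]), spec$spot_sigma,
                      spec$peak_intensity)
    }
    image <- img[1, , ]
    if (spec$noise_sd > 0) {
      image <- image + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
    }
    list(image = image, truth = data.frame(x = x, y = y))
  })
}

#' Specification of a random disk particle field
#'
#' Emulates thresholded puncta images (dye-labeled myelin particles,
#' cathepsin-activity puncta): uniformly placed non-overlapping disks of
#' random radius on a dark background.
#'
#' @param image_shape Image dimensions `c(height, width)` in pixels.
#' @param n_particles Number of disks.
#' @param radius_mean,radius_sd Disk radius distribution (pixels).
#' @param intensity Disk intensity (a.u.).
#' @param noise_sd Additive Gaussian noise sd (a.u.).
#' @param seed Integer RNG seed.
#' @return An object of class `"particle_field_spec"`.
#' @export
particle_field_spec <- function(image_shape = c(128, 128), n_particles = 20,
                                radius_mean = 4, radius_sd = 1,
                                intensity = 100, noise_sd = 0, seed = 1) {
  stop_if_not(radius_mean > 0, "radius_mean must be > 0")
  stop_if_not(n_particles >= 0, "n_particles must be >= 0")
  structure(as.list(environment()), class = "particle_field_spec")
}

#' Generate a particle field with per-particle ground truth
#'
#' Disks are placed at integer pixel centers without overlap (rejection
#' sampling; an error is raised if the requested density is infeasible),
#' so equal radii rasterize to equal pixel areas. The truth table records
#' each particle's rasterized pixel area, the oracle for downstream
#' particle statistics.
#'
#' @param spec A [particle_field_spec()].
#' @return A list with `image` (matrix, (y, x)) and `truth` (data.frame:
#'   `x`, `y`, `radius`, `area_px`).
#' @export
make_particle_field <- function(spec) {
  stopifnot(inherits(spec, "particle_field_spec"))
  h <- spec$image_shape[1]
  w <- spec$image_shape[2]
  with_seed(spec$seed, {
    img <- matrix(0, h, w)
    placed <- data.frame(x = numeric(0), y = numeric(0), radius = numeric(0),
                         area_px = integer(0))
    tries <- 0L
    while (nrow(placed) < spec$n_particles) {
      tries <- tries + 1L
      if (tries > 20000L) {
        stop("placement failure: could not place non-overlapping particles",
             call. = FALSE)
      }
      r <- max(0.5, stats::rnorm(1, spec$radius_mean, spec$radius_sd))
      cx <- round(stats::runif(1, r + 1, w - r))
      cy <- round(stats::runif(1, r + 1, h - r))
      if (nrow(placed) > 0 &&
          any(sqrt((placed$x - cx)^2 + (placed$y - cy)^2) <
              placed$radius + r + 2)) next
      xs <- floor(cx - r):ceiling(cx + r)
      ys <- floor(cy - r):ceiling(cy + r)
      px <- expand.grid(y = ys, x = xs)
      inside <- (px$x - cx)^2 + (px$y - cy)^2 <= r^2
      px <- px[inside, , drop = FALSE]
      img[cbind(px$y, px$x)] <- spec$intensity
      placed <- rbind(placed, data.frame(x = cx, y = cy, radius = r,
                                         area_px = nrow(px)))
    }
    if (spec$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
    }
    list(image = img, truth = placed)
  })
}
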