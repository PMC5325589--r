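# Object-based quantification: 3D connected-component labeling (the
# object-counter step), 2D particle statistics, and per-cell intensity
# readouts.

# Neighbor offsets for 3D connectivity 6 (faces), 18 (faces+edges),
# 26 (faces+edges+corners).
connectivity_offsets <- function(connectivity) {
  stop_if_not(connectivity %in% c(6, 18, 26),
              "connectivity must be one of 6, 18, 26")
  off <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  nz <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6"  = nz == 1,
                 "18" = nz >= 1 & rowSums(abs(off) > 0) <= 2,
                 "26" = nz >= 1)
  off[keep, , drop = FALSE]
}

#' Label connected components in a 3D mask
#'
#' Breadth-first connected-component labeling of a boolean volume under
#' 6-, 18- or 26-connectivity (26 is the conventional default of 3D
#' object counters). A 2D mask is treated as a single-slice volume, where
#' 26-connectivity reduces to 2D 8-connectivity and 6 to 4-connectivity.
#'
#' @param mask Logical 3D array (z, y, x) or 2D matrix.
#' @param connectivity 6, 18 or 26.
#' @return A list: `labels` (integer array, 0 = background, objects
#'   numbered contiguously from 1 in first-voxel raster order) and
#'   `table`, an object table data.frame with one row per object:
#'   `label`, `volume` (voxel count), `centroid_z`, `centroid_y`,
#'   `centroid_x` (1-based voxel coordinates).
#' @export
label_objects <- function(mask, connectivity = 26) {
  if (is.matrix(mask)) mask <- array(mask, c(1, dim(mask)))
  stop_if_not(length(dim(mask)) == 3, "mask must be 2D or 3D")
  d <- dim(mask)
  off <- connectivity_offsets(connectivity)
  lab <- array(0L, d)
  fg <- which(mask)
  lab_count <- 0L
  # precompute index arithmetic: linear index = z + (y-1)*nz + (x-1)*nz*ny
  nz <- d[1]; ny <- d[2]
  for (start in fg) {
    if (lab[start] != 0L) next
    lab_count <- lab_count + 1L
    queue <- start
    lab[start] <- lab_count
    while (length(queue) > 0) {
      cur <- queue
      queue <- integer(0)
      z <- ((cur - 1L) %% nz) + 1L
      y <- (((cur - 1L) %/% nz) %% ny) + 1L
      x <- ((cur - 1L) %/% (nz * ny)) + 1L
      for (k in seq_len(nrow(off))) {
        zz <- z + off[k, 1]; yy <- y + off[k, 2]; xx <- x + off[k, 3]
        ok <- zz >= 1 & zz <= d[1] & yy >= 1 & yy <= d[2] &
          xx >= 1 & xx <= d[3]
        if (!any(ok)) next
        nb <- zz[ok] + (yy[ok] - 1L) * nz + (xx[ok] - 1L) * nz * ny
        nb <- nb[mask[nb] & lab[nb] == 0L]
        if (length(nb) > 0) {
          nb <- unique(nb)
          lab[nb] <- lab_count
          queue <- c(queue, nb)
        }
      }
    }
  }
  if (lab_count == 0L) {
    return(list(labels = lab,
                table = data.frame(label = integer(0), volume = integer(0),
                                   centroid_z = numeric(0),
                                   centroid_y = numeric(0),
                                   centroid_x = numeric(0))))
  }
  idx <- which(lab > 0L)
  l <- lab[idx]
  z <- ((idx - 1L) %% nz) + 1L
  y <- (((idx - 1L) %/% nz) %% ny) + 1L
  x <- ((idx - 1L) %/% (nz * ny)) + 1L
  tab <- data.frame(
    label = seq_len(lab_count),
    volume = as.integer(tabulate(l, lab_count)),
    centroid_z = as.numeric(tapply(z, l, mean)),
    centroid_y = as.numeric(tapply(y, l, mean)),
    centroid_x = as.numeric(tapply(x, l, mean))
  )
  list(labels = lab, table = tab)
}

#' Per-object mean intensity
#'
#' Adds per-channel mean intensities to an object table.
#'
#' @param labels Integer label array from [label_objects()].
#' @param ... Named intensity arrays of the same shape.
#' @return data.frame: `label` plus one `mean_<name>` column per channel.
#' @export
object_intensities <- function(labels, ...) {
  channels <- list(...)
  stop_if_not(length(channels) > 0, "supply at least one intensity array")
  n <- max(labels)
  idx <- which(labels > 0L)
  l <- labels[idx]
  out <- data.frame(label = seq_len(n))
  for (nm in names(channels)) {
    stop_if_not(identical(dim(channels[[nm]]), dim(labels)),
                "channel shape differs from labels")
    out[[paste0("mean_", nm)]] <-
      as.numeric(tapply(channels[[nm]][idx], l, mean))
  }
  out
}

#' Summarize an object table with a minimum-volume filter
#'
#' @param table Object table from [label_objects()].
#' @param min_volume Minimum object volume (voxels) to retain; >= 1.
#' @return A list: `count`, `volumes` (retained volumes), `mean_volume`
#'   (`NA` when no object survives, with a warning).
#' @export
object_summary <- function(table, min_volume = 1) {
  stop_if_not(min_volume >= 1, "min_volume must be >= 1")
  keep <- table$volume >= min_volume
  vols <- table$volume[keep]
  mean_volume <- if (length(vols) > 0) mean(vols) else {
    warning("no objects survive the volume filter; mean volume undefined")
    NA_real_
  }
  list(count = length(vols), volumes = vols, mean_volume = mean_volume)
}

#' 2D particle statistics from a thresholded image
#'
#' Threshold, 8-connected component labeling, and a minimum-size filter;
#' the standard count-and-size readout for puncta/particle images
#' (dye-labeled myelin, cathepsin-activity puncta).
#'
#' @param image 2D intensity matrix.
#' @param threshold Numeric manual threshold, or `"otsu"`.
#' @param min_size Minimum particle area (pixels) to retain; default 4
#'   suppresses single-pixel noise.
#' @return A list of class `"particle_stats"`: `count`, `mean_size`
#'   (`NA` if no particle), `size_list` (pixel areas), `threshold`.
#' @export
particle_stats_2d <- function(image, threshold = "otsu", min_size = 4) {
  stop_if_not(is.matrix(image), "image must be a 2D matrix")
  mask <- threshold_channel(image, threshold)
  thr <- attr(mask, "threshold")
  lab <- label_objects(matrix(mask, nrow(image), ncol(image)),
                       connectivity = 26)
  sizes <- lab$table$volume[lab$table$volume >= min_size]
  structure(list(count = length(sizes),
                 mean_size = if (length(sizes) > 0) mean(sizes) else NA_real_,
                 size_list = sizes, threshold = thr),
            class = "particle_stats")
}

#' Per-cell raw integrated intensity
#'
#' Sums intensities within each cell mask; cells with empty masks are
#' reported as zero with a warning (flagged, not dropped).
#'
#' @param image Intensity matrix or array.
#' @param cell_masks Named list of disjoint logical masks, one per cell.
#' @return data.frame: `cell`, `integrated_intensity`, `n_pixels`.
#' @export
per_cell_intensity <- function(image, cell_masks) {
  stop_if_not(length(cell_masks) > 0, "no cell masks supplied")
  total <- Reduce(`+`, lapply(cell_masks, function(m) as.integer(m)))
  stop_if_not(max(total) <= 1, "cell masks must be disjoint")
  cells <- names(cell_masks)
  if (is.null(cells)) cells <- as.character(seq_along(cell_masks))
  n_px <- vapply(cell_masks, sum, numeric(1))
  if (any(n_px == 0)) warning("empty cell mask(s): intensity reported as 0")
  data.frame(
    cell = cells,
    integrated_intensity = vapply(cell_masks, function(m) sum(image[m]),
                                  numeric(1)),
    n_pixels = as.numeric(n_px),
    stringsAsFactors = FALSE
  )
}

#' Fold change of group means relative to a reference group
#'
#' `mean(group) / mean(reference)` for each group, the conventional
#' normalized-intensity readout (e.g. signal fold change relative to the
#' wild-type control).
#'
#' @param values Numeric per-cell values.
#' @param groups Group label per value.
#' @param reference Reference group label.
#' @return data.frame: `group`, `mean`, `fold_change`.
#' @export
fold_change <- function(values, groups, reference) {
  stop_if_not(reference %in% groups, "reference group not present")
  m <- tapply(values, groups, mean)
  ref <- m[[reference]]
  if (!is.finite(ref) || ref == 0) {
    stop("fold change undefined: reference group mean is zero",
         call. = FALSE)
  }
  data.frame(group = names(m), mean = as.numeric(m),
             fold_change = as.numeric(m) / ref,
             stringsAsFactors = FALSE)
}
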