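# Lysosomal pH estimation. Single-lysosome route: emission spectrum ->
# Weibull-5 peak fit -> 470/524 nm ratio -> linear calibration -> pH,
# plus ApoD classification and pH frequency distributions. Population
# route: F340/F390 excitation ratios inverted through an interpolated
# ionophore-clamp calibration.

#' Fit a five-parameter Weibull peak to an emission spectrum
#'
#' Nonlinear least squares (Levenberg-Marquardt, \pkg{minpack.lm}) with
#' multi-start initialization: the peak position starts at the brightest
#' sample, the baseline at the minimum intensity, the amplitude at the
#' intensity range, the width at half the spectral span, and the shape
#' parameter at each of 1.5, 2.2 and 3.0; the start with the lowest
#' residual sum of squares wins. Bounds keep `b > 0` and `c > 1`.
#'
#' @param wavelength Wavelengths (nm), strictly increasing, >= 8 samples.
#' @param intensity Intensities (a.u.), same length.
#' @param init Optional named list/vector with starting values
#'   (`y0`, `a`, `x0`, `b`, `c`); used as an additional start.
#' @return An object of class `"weibull5_fit"`: `y0`, `a`, `x0`, `b`, `c`,
#'   `rss`, `converged`. The fitted curve attains `y0 + a` at `x0`.
#' @export
fit_weibull5 <- function(wavelength, intensity, init = NULL) {
  stop_if_not(length(wavelength) == length(intensity),
              "wavelength and intensity lengths differ")
  stop_if_not(length(wavelength) >= 8,
              "need at least 8 samples for a 5-parameter fit")
  stop_if_not(!is.unsorted(wavelength, strictly = TRUE),
              "wavelengths must be strictly increasing")
  stop_if_not(all(is.finite(intensity)), "intensities must be finite")
  rng <- diff(range(intensity))
  if (rng <= 0) stop("no peak: flat spectrum", call. = FALSE)
  span <- diff(range(wavelength))
  starts <- lapply(c(1.5, 2.2, 3.0), function(cc) {
    list(y0 = min(intensity), a = rng,
         x0 = wavelength[which.max(intensity)], b = span / 2, cc = cc)
  })
  if (!is.null(init)) {
    init <- as.list(init)
    starts <- c(list(list(y0 = init$y0, a = init$a, x0 = init$x0,
                          b = init$b, cc = init$c)), starts)
  }
  lower <- c(y0 = -Inf, a = 1e-9, x0 = min(wavelength) - span,
             b = 1e-3, cc = 1 + 1e-6)
  best <- NULL
  best_rss <- Inf
  any_converged <- FALSE
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        intensity ~ weibull5(wavelength, y0, a, x0, b, cc),
        start = st, lower = lower,
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    conv <- fit$convInfo$isConv
    if (rss < best_rss) {
      best <- stats::coef(fit)
      best_rss <- rss
      any_converged <- conv
    }
  }
  if (is.null(best)) {
    stop("Weibull-5 fit failed from every start", call. = FALSE)
  }
  structure(list(y0 = unname(best["y0"]), a = unname(best["a"]),
                 x0 = unname(best["x0"]), b = unname(best["b"]),
                 c = unname(best["cc"]), rss = best_rss,
                 converged = isTRUE(any_converged)),
            class = "weibull5_fit")
}

#' Evaluate a fitted Weibull-5 curve
#' @param object A `"weibull5_fit"`.
#' @param wavelength Wavelengths (nm) at which to evaluate.
#' @param ... Unused.
#' @return Fitted intensities.
#' @export
predict.weibull5_fit <- function(object, wavelength, ...) {
  weibull5(wavelength, object$y0, object$a, object$x0, object$b, object$c)
}

#' Emission 470/524 nm ratio of a fitted spectrum
#'
#' The ratiometric pH readout of the single-lysosome pipeline: the fitted
#' curve evaluated at 470 nm divided by its value at 524 nm.
#'
#' @param fit A `"weibull5_fit"` (should have converged).
#' @param num_nm,den_nm Numerator and denominator wavelengths (nm).
#' @return Dimensionless ratio.
#' @export
emission_ratio <- function(fit, num_nm = 470, den_nm = 524) {
  stopifnot(inherits(fit, "weibull5_fit"))
  den <- predict(fit, den_nm)
  if (den <= 0) stop("invalid denominator: fitted intensity at ",
                     den_nm, " nm is not positive", call. = FALSE)
  predict(fit, num_nm) / den
}

#' Linear emission-ratio calibration from clamped standards
#'
#' Ordinary least-squares line `ratio = slope * pH + intercept` through
#' ionophore-clamped standards, the calibration model for the dye's
#' linear regime (pH 4.0--5.5). Standards must be strictly monotone in
#' pH, otherwise the curve is not invertible.
#'
#' @param standards data.frame with columns `ph` and `ratio` (or two
#'   numeric vectors via `ph=`/`ratio=`).
#' @param ph,ratio Alternative vector interface.
#' @return An object of class `"calibration_curve"` with `mode =
#'   "emission_linear"`, `slope`, `intercept`, `valid_ph_range`, `fit_r2`.
#' @export
fit_emission_calibration <- function(standards = NULL, ph = NULL,
                                     ratio = NULL) {
  if (!is.null(standards)) {
    ph <- standards$ph
    ratio <- standards$ratio
  }
  stop_if_not(length(ph) == length(ratio), "ph and ratio lengths differ")
  if (length(unique(ph)) < 2) {
    stop("calibration underdetermined: need >= 2 distinct pH levels",
         call. = FALSE)
  }
  ord <- order(ph)
  r <- ratio[ord]
  if (!(all(diff(r) > 0) || all(diff(r) < 0))) {
    stop("calibration not invertible: standards are not strictly monotone",
         call. = FALSE)
  }
  fit <- stats::lm(ratio ~ ph)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((ratio - mean(ratio))^2)
  r2 <- 1 - ss_res / ss_tot
  structure(list(mode = "emission_linear",
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 valid_ph_range = range(ph),
                 fit_r2 = r2),
            class = "calibration_curve")
}

#' Interpolated excitation-ratio calibration from clamped standards
#'
#' Monotone piecewise-linear map between pH and F340/F390 ratio through
#' the clamped standards; no functional form is assumed, appropriate for
#' the sigmoid plate-reader calibration curves.
#'
#' @inheritParams fit_emission_calibration
#' @return A `"calibration_curve"` with `mode = "excitation_interp"` and
#'   `knots` (data.frame `ph`, `ratio` sorted by pH).
#' @export
fit_excitation_calibration <- function(standards = NULL, ph = NULL,
                                       ratio = NULL) {
  if (!is.null(standards)) {
    ph <- standards$ph
    ratio <- standards$ratio
  }
  if (length(unique(ph)) < 3) {
    stop("calibration underdetermined: need >= 3 distinct pH levels",
         call. = FALSE)
  }
  ord <- order(ph)
  knots <- data.frame(ph = ph[ord], ratio = ratio[ord])
  if (!(all(diff(knots$ratio) > 0) || all(diff(knots$ratio) < 0))) {
    stop("calibration not invertible: standards are not strictly monotone",
         call. = FALSE)
  }
  structure(list(mode = "excitation_interp", knots = knots,
                 valid_ph_range = range(ph), fit_r2 = NA_real_),
            class = "calibration_curve")
}

#' Invert a calibration curve: ratio to pH
#'
#' Linear mode inverts the fitted line; interpolation mode inverts the
#' monotone piecewise-linear map. Estimates falling outside the
#' calibration's valid pH range are clamped to the nearer boundary and
#' flagged (readings at the edge of the probe's dynamic range).
#' Clamping is idempotent.
#'
#' @param curve A `"calibration_curve"`.
#' @param ratio Numeric vector of measured ratios.
#' @return data.frame: `ratio`, `ph`, `clamped`.
#' @export
ratio_to_ph <- function(curve, ratio) {
  stopifnot(inherits(curve, "calibration_curve"))
  rng <- curve$valid_ph_range
  if (curve$mode == "emission_linear") {
    ph <- (ratio - curve$intercept) / curve$slope
    clamped <- ph < rng[1] | ph > rng[2]
  } else {
    k <- curve$knots
    # approx() requires increasing x; use ratio as x, pH as y
    ord <- order(k$ratio)
    ph <- stats::approx(k$ratio[ord], k$ph[ord], xout = ratio,
                        rule = 2)$y
    clamped <- ratio < min(k$ratio) | ratio > max(k$ratio)
  }
  ph <- pmin(pmax(ph, rng[1]), rng[2])
  data.frame(ratio = ratio, ph = ph, clamped = clamped)
}

#' Classify lysosome ROIs as ApoD-positive
#'
#' A lysosome is ApoD-positive when the mean immunolabel intensity within
#' its ROI exceeds the threshold.
#'
#' @param roi_masks Logical mask, or list of logical masks (one per
#'   lysosome ROI), each matching `apod_image` in shape.
#' @param apod_image Immunolabel intensity image/stack.
#' @param threshold Mean-intensity cutoff (a.u.).
#' @return Logical vector, one element per ROI.
#' @export
classify_apod <- function(roi_masks, apod_image, threshold) {
  if (!is.list(roi_masks)) roi_masks <- list(roi_masks)
  vapply(roi_masks, function(m) {
    stop_if_not(identical(dim(m), dim(apod_image)),
                "ROI shape differs from image")
    if (sum(m) == 0) stop("empty ROI", call. = FALSE)
    mean(apod_image[m]) > threshold
  }, logical(1))
}

#' Estimate per-lysosome pH from emission spectra
#'
#' Runs the full single-lysosome pipeline over a long-format spectra
#' table: per-lysosome Weibull-5 fit, 470/524 ratio on the fitted curve,
#' and calibration inversion.
#'
#' @param spectra Long data.frame with `lysosome_id`, `wavelength_nm`,
#'   `intensity` (and optionally `condition`, `class`, carried through).
#' @param curve An emission-mode `"calibration_curve"`.
#' @return data.frame of lysosome records: `lysosome_id`,
#'   `ratio_470_524`, `ph`, `clamped`, `converged` (+ carried labels).
#' @export
estimate_lysosome_ph <- function(spectra, curve) {
  ids <- unique(spectra$lysosome_id)
  rows <- lapply(ids, function(id) {
    s <- spectra[spectra$lysosome_id == id, ]
    fit <- fit_weibull5(s$wavelength_nm, s$intensity)
    r <- emission_ratio(fit)
    est <- ratio_to_ph(curve, r)
    out <- data.frame(lysosome_id = id, ratio_470_524 = r, ph = est$ph,
                      clamped = est$clamped, converged = fit$converged)
    for (lbl in intersect(c("condition", "class"), names(s))) {
      out[[lbl]] <- s[[lbl]][1]
    }
    out
  })
  do.call(rbind, rows)
}

# Bin index (1-based) on bins of width bw aligned at pH 4.0; tolerant of
# floating-point values sitting on bin edges.
ph_bin_index <- function(ph, bw) floor((ph - 4.0) / bw + 1e-6)

#' pH frequency distribution and modal bin
#'
#' Histograms pH values on bins of width `bin_width` aligned at pH 4.0
#' and reports the center of the most populated bin per group; ties are
#' broken toward lower pH.
#'
#' @param records data.frame with column `ph` (and optional grouping
#'   columns among `condition`, `class`), or a bare numeric vector.
#' @param bin_width Bin width in pH units (default 0.1).
#' @return A list: `histogram` (group columns, `bin_lo`, `bin_center`,
#'   `count`) and `modes` (group columns, `mode_center`, `n`).
#' @export
ph_distribution <- function(records, bin_width = 0.1) {
  if (is.numeric(records)) records <- data.frame(ph = records)
  stop_if_not(nrow(records) >= 1, "no records")
  by_cols <- intersect(c("condition", "class"), names(records))
  if (length(by_cols) == 0) {
    records$group <- "all"
    by_cols <- "group"
  }
  key <- interaction(records[by_cols], drop = TRUE, sep = " / ")
  hist_rows <- list()
  mode_rows <- list()
  for (g in levels(key)) {
    ph <- records$ph[key == g]
    if (length(ph) == 0) {
      warning("empty class omitted: ", g)
      next
    }
    bins <- ph_bin_index(ph, bin_width)
    tab <- table(bins)
    b <- as.integer(names(tab))
    cnt <- as.integer(tab)
    modal_bin <- min(b[cnt == max(cnt)]) # tie toward lower pH
    lbl <- records[match(g, key), by_cols, drop = FALSE]
    hist_rows[[g]] <- cbind(lbl[rep(1, length(b)), , drop = FALSE],
                            data.frame(bin_lo = 4.0 + b * bin_width,
                                       bin_center = 4.0 + (b + 0.5) * bin_width,
                                       count = cnt),
                            row.names = NULL)
    mode_rows[[g]] <- cbind(lbl,
                            data.frame(mode_center = 4.0 +
                                         (modal_bin + 0.5) * bin_width,
                                       n = length(ph)),
                            row.names = NULL)
  }
  list(histogram = do.call(rbind, c(hist_rows, list(make.row.names = FALSE))),
       modes = do.call(rbind, c(mode_rows, list(make.row.names = FALSE))))
}

#' Proportions of ApoD-positive and negative lysosomes per condition
#'
#' @param records data.frame with logical `apod_positive` and `condition`.
#' @return data.frame: `condition`, `n`, `frac_positive`, `frac_negative`
#'   (the two fractions sum to 1 per condition).
#' @export
apod_lysosome_fractions <- function(records) {
  stop_if_not(all(c("apod_positive", "condition") %in% names(records)),
              "records need apod_positive and condition columns")
  conds <- unique(records$condition)
  do.call(rbind, lapply(conds, function(cond) {
    r <- records[records$condition == cond, ]
    n <- nrow(r)
    fp <- mean(r$apod_positive)
    data.frame(condition = cond, n = n, frac_positive = fp,
               frac_negative = 1 - fp, stringsAsFactors = FALSE)
  }))
}

#' Population lysosomal pH from excitation-ratio plate readings
#'
#' Per-well ratio = mean(F340 reads) / mean(F390 reads) (the assay
#' averages six replicate measurements per well), inverted through a
#' monotone piecewise-linear calibration built from ionophore-clamped
#' standards. Out-of-range ratios are clamped to the calibration
#' boundary and flagged.
#'
#' @param f340,f390 Per-well readings: numeric vectors (one well) or
#'   lists of numeric vectors (one element per well) of matched lengths.
#' @param standards data.frame with `ph` and `ratio` covering >= 3 levels.
#' @return data.frame: `well`, `ratio`, `ph`, `clamped`.
#' @export
population_ph_excitation <- function(f340, f390, standards) {
  if (!is.list(f340)) f340 <- list(f340)
  if (!is.list(f390)) f390 <- list(f390)
  stop_if_not(length(f340) == length(f390),
              "f340 and f390 well counts differ")
  curve <- fit_excitation_calibration(standards)
  wells <- names(f340)
  if (is.null(wells)) wells <- as.character(seq_along(f340))
  ratios <- vapply(seq_along(f340), function(i) {
    stop_if_not(length(f340[[i]]) == length(f390[[i]]),
                "matched f340/f390 read counts required")
    m390 <- mean(f390[[i]])
    if (m390 == 0) stop("zero F390 signal in well ", wells[i],
                        call. = FALSE)
    mean(f340[[i]]) / m390
  }, numeric(1))
  est <- ratio_to_ph(curve, ratios)
  data.frame(well = wells, ratio = ratios, ph = est$ph,
             clamped = est$clamped, stringsAsFactors = FALSE)
}
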