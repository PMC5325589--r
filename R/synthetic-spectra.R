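# Synthetic emission-spectrum generator: the dye model behind the
# single-lysosome pH pipeline, with known ground truth.

#' Condition defaults for the synthetic spectral ground truth
#'
#' Modal pH per condition and ApoD class, mirroring the reported frequency
#' distributions: under control (and low-serum) conditions ApoD-positive
#' lysosomes peak at pH 4.7 and ApoD-negative lysosomes at 4.4; a 2 h
#' paraquat insult shifts ApoD-positive lysosomes by +0.5 units (to 5.2)
#' and ApoD-negative ones by +0.2 (to 4.6); after 24 h the ApoD-positive
#' pool reverses to 4.7 while the ApoD-negative shift persists. Spreads
#' emulate the "narrow" ApoD-negative versus "broad" ApoD-positive
#' distributions and are configuration, not measured values.
#'
#' @format A data.frame with columns `condition`, `class`, `ph_mode`, `ph_sd`.
#' @export
ph_condition_defaults <- function() {
  data.frame(
    condition = rep(c("control", "LS", "PQ2h", "PQ24h"), each = 2),
    class     = rep(c("ApoD+", "ApoD-"), times = 4),
    ph_mode   = c(4.7, 4.4, 4.7, 4.4, 5.2, 4.6, 4.7, 4.6),
    ph_sd     = rep(c(0.25, 0.08), times = 4),
    stringsAsFactors = FALSE
  )
}

#' Ground-truth specification for synthetic emission spectra
#'
#' Bundles the spectral model (five-parameter Weibull peak whose position
#' shifts with pH), the pH distribution of the simulated lysosome
#' population, and the noise level. Defaults for `ph_mode`/`ph_sd` are
#' looked up from [ph_condition_defaults()] by `condition` and `class`.
#'
#' The nominal peak-position map is linear, `x0 = peak_map_intercept +
#' peak_map_slope * pH` (defaults place the peak at 470 nm at pH 4.0,
#' moving +18 nm per pH unit). Peak placement is refined so that the
#' 470/524 nm intensity ratio is exactly linear in pH over the dye's
#' dynamic range 4.0--5.5 (see [emission_peak_position()]), which is the
#' regime in which a linear ratio--pH calibration is exact; above 5.5 the
#' peak continues along the nominal linear map and the ratio saturates.
#'
#' @param condition One of `"control"`, `"LS"`, `"PQ2h"`, `"PQ24h"`.
#' @param class `"ApoD+"` or `"ApoD-"`.
#' @param ph_mode,ph_sd Mode and spread (pH units) of the truncated-normal
#'   pH distribution on \[4.0, 6.0\]; defaults from the condition table.
#' @param peak_map_slope Peak shift per pH unit (nm); 0 produces a
#'   pH-insensitive (degenerate) dye.
#' @param peak_map_intercept Intercept of the nominal linear map (nm).
#' @param weibull_a,weibull_b,weibull_c,weibull_y0 Spectral shape defaults.
#' @param noise_sd Additive Gaussian noise on intensities (a.u.).
#' @param n_lysosomes Number of simulated lysosomes.
#' @param seed Integer RNG seed; identical spec implies identical output.
#' @return An object of class `"spectrum_ground_truth"` (a list).
#' @export
spectrum_ground_truth <- function(condition = "control", class = "ApoD+",
                                  ph_mode = NULL, ph_sd = NULL,
                                  peak_map_slope = 18,
                                  peak_map_intercept = 398,
                                  weibull_a = 100, weibull_b = 60,
                                  weibull_c = 2.2, weibull_y0 = 5,
                                  noise_sd = 2, n_lysosomes = 30, seed = 1) {
  defaults <- ph_condition_defaults()
  row <- defaults[defaults$condition == condition & defaults$class == class, ]
  if (is.null(ph_mode)) {
    stop_if_not(nrow(row) == 1,
                sprintf("no pH defaults for condition '%s' / class '%s'",
                        condition, class))
    ph_mode <- row$ph_mode
  }
  if (is.null(ph_sd)) ph_sd <- if (nrow(row) == 1) row$ph_sd else 0.1
  stop_if_not(ph_mode >= 4.0 && ph_mode <= 6.0,
              "ph_mode must lie within [4.0, 6.0]")
  stop_if_not(weibull_c > 1, "weibull_c must be > 1")
  stop_if_not(n_lysosomes >= 1, "n_lysosomes must be >= 1")
  stop_if_not(noise_sd >= 0, "noise_sd must be >= 0")
  structure(list(
    condition = condition, class = class,
    ph_mode = ph_mode, ph_sd = ph_sd,
    peak_map_slope = peak_map_slope,
    peak_map_intercept = peak_map_intercept,
    weibull_a = weibull_a, weibull_b = weibull_b,
    weibull_c = weibull_c, weibull_y0 = weibull_y0,
    noise_sd = noise_sd, n_lysosomes = n_lysosomes, seed = seed
  ), class = "spectrum_ground_truth")
}

# 470/524 intensity ratio of the noiseless spectral model at peak position x0.
ratio_at_peak <- function(x0, gt) {
  weibull5(470, gt$weibull_y0, gt$weibull_a, x0, gt$weibull_b, gt$weibull_c) /
    weibull5(524, gt$weibull_y0, gt$weibull_a, x0, gt$weibull_b, gt$weibull_c)
}

#' Peak position of the synthetic dye at a given pH
#'
#' Within the dye's dynamic range (pH 4.0--5.5) the peak is placed so that
#' the noiseless 470/524 nm ratio is exactly linear in pH, anchored at the
#' nominal map's endpoints (`x0(4.0)` and `x0(5.5)` from the linear map
#' `peak_map_intercept + peak_map_slope * pH`). This emulates a ratiometric
#' dye whose calibration is empirically linear over its dynamic range, and
#' makes the noiseless round trip through a linear calibration exact.
#' Above pH 5.5 the peak continues along the nominal linear map (ratio
#' response saturates, as at the edge of a probe's dynamic range).
#'
#' With `peak_map_slope = 0` the peak does not move with pH (degenerate,
#' pH-insensitive dye); downstream calibration must reject such standards.
#'
#' @param ph Numeric vector of pH values in \[4.0, 6.0\].
#' @param gt A [spectrum_ground_truth()] object.
#' @return Peak positions (nm), same length as `ph`.
#' @export
emission_peak_position <- function(ph, gt) {
  slope <- gt$peak_map_slope
  x0_nominal <- gt$peak_map_intercept + slope * ph
  if (slope == 0) return(x0_nominal)
  x_lo <- gt$peak_map_intercept + slope * 4.0
  x_hi <- gt$peak_map_intercept + slope * 5.5
  r_lo <- ratio_at_peak(x_lo, gt)
  r_hi <- ratio_at_peak(x_hi, gt)
  target <- r_lo + (pmin(ph, 5.5) - 4.0) / 1.5 * (r_hi - r_lo)
  lo <- min(x_lo, x_hi)
  hi <- max(x_lo, x_hi)
  out <- x0_nominal
  idx <- which(ph <= 5.5)
  for (i in idx) {
    out[i] <- stats::uniroot(function(x) ratio_at_peak(x, gt) - target[i],
                             lower = lo, upper = hi, tol = 1e-10)$root
  }
  out
}

#' Standard emission-scan wavelengths (420--700 nm every 10 nm)
#' @return Numeric vector of 29 wavelengths (nm).
#' @export
emission_wavelengths <- function() seq(420, 700, by = 10)

#' Generate synthetic single-lysosome emission spectra
#'
#' Draws each lysosome's true pH from a truncated Normal on \[4.0, 6.0\],
#' evaluates the Weibull-5 spectral model at the scan wavelengths with the
#' pH-dependent peak position, and adds Gaussian noise.
#'
#' @param gt A [spectrum_ground_truth()] object.
#' @return A list with `spectra` (long data.frame: `lysosome_id`,
#'   `wavelength_nm`, `intensity`, `condition`, `class`) and `truth`
#'   (data.frame: `lysosome_id`, `true_ph`, `peak_nm`).
#' @export
make_spectra <- function(gt) {
  stopifnot(inherits(gt, "spectrum_ground_truth"))
  wl <- emission_wavelengths()
  with_seed(gt$seed, {
    ph <- rnorm_trunc(gt$n_lysosomes, gt$ph_mode, gt$ph_sd, 4.0, 6.0)
    x0 <- emission_peak_position(ph, gt)
    spectra <- do.call(rbind, lapply(seq_len(gt$n_lysosomes), function(i) {
      y <- weibull5(wl, gt$weibull_y0, gt$weibull_a, x0[i],
                    gt$weibull_b, gt$weibull_c)
      if (gt$noise_sd > 0) y <- y + stats::rnorm(length(wl), 0, gt$noise_sd)
      data.frame(lysosome_id = i, wavelength_nm = wl, intensity = y,
                 condition = gt$condition, class = gt$class,
                 stringsAsFactors = FALSE)
    }))
    list(spectra = spectra,
         truth = data.frame(lysosome_id = seq_len(gt$n_lysosomes),
                            true_ph = ph, peak_nm = x0))
  })
}

#' Generate ionophore-clamped calibration standard spectra
#'
#' Emulates lysosomes equilibrated to known extracellular pH with
#' monensin/nigericin: one (near-)noiseless spectrum per clamped pH level,
#' using the same spectral model as [make_spectra()].
#'
#' @param gt A [spectrum_ground_truth()] object (spectral shape is used;
#'   its pH distribution is ignored).
#' @param ph_levels Clamped pH values, each within \[4.0, 6.0\]. Default
#'   covers the dye's linear regime 4.0--5.5 in 0.5 steps.
#' @param noise_sd Noise on standard spectra (a.u.); default 0.
#' @return data.frame with `ph`, `wavelength_nm`, `intensity`.
#' @export
make_calibration_standards <- function(gt, ph_levels = c(4.0, 4.5, 5.0, 5.5),
                                       noise_sd = 0) {
  stopifnot(inherits(gt, "spectrum_ground_truth"))
  stop_if_not(length(ph_levels) >= 1, "ph_levels must be non-empty")
  stop_if_not(all(ph_levels >= 4.0 & ph_levels <= 6.0),
              "ph_levels must lie within [4.0, 6.0]")
  wl <- emission_wavelengths()
  x0 <- emission_peak_position(ph_levels, gt)
  with_seed(gt$seed, {
    do.call(rbind, lapply(seq_along(ph_levels), function(i) {
      y <- weibull5(wl, gt$weibull_y0, gt$weibull_a, x0[i],
                    gt$weibull_b, gt$weibull_c)
      if (noise_sd > 0) y <- y + stats::rnorm(length(wl), 0, noise_sd)
      data.frame(ph = ph_levels[i], wavelength_nm = wl, intensity = y)
    }))
  })
}

#' Population excitation-ratio dye model
#'
#' Sigmoid F340/F390 excitation ratio as a function of pH, emulating the
#' plate-reader calibration curves of a ratiometric dye over its working
#' range: monotone decreasing, steepest near the pKa (set at pH 5.0).
#' Configuration, not a fitted curve.
#'
#' @param ph Numeric vector of pH values.
#' @return Excitation ratios (dimensionless).
#' @export
excitation_ratio_model <- function(ph) {
  0.4 + 2.2 / (1 + exp(1.8 * (ph - 5.0)))
}

#' Population pH defaults per condition (excitation plate assay)
#'
#' True mean lysosomal pH per well condition for the synthetic plate
#' generator: control and low-serum wells at pH 4.6; a 2 h paraquat insult
#' alkalinizes the compartment by +0.5 units (5.1); chloroquine, the
#' positive control for alkalinization, by +0.9 (5.5). Configuration
#' values, chosen to reproduce the reported average PQ-induced increase.
#'
#' @return Named numeric vector of well pH values.
#' @export
population_ph_defaults <- function() {
  c(control = 4.6, LS = 4.6, PQ2h = 5.1, CQ = 5.5)
}

#' Simulate F340/F390 excitation plate readings
#'
#' Generates six replicate F340 and F390 intensity readings per well (the
#' mean of six measurements is the assay's per-well datum) for wells of
#' known true pH, plus clamped calibration standards.
#'
#' @param well_ph Named numeric vector: true pH per treatment well.
#' @param standard_ph Clamped pH levels for calibration wells (default
#'   4.0--6.0 in 0.5 steps).
#' @param n_reads Replicate measurements per well (default 6).
#' @param noise_sd Relative (fractional) Gaussian noise on each reading.
#' @param f390_level Baseline F390 intensity (a.u.).
#' @param seed Integer RNG seed.
#' @return A list with `wells` (data.frame: `well`, `read`, `f340`,
#'   `f390`, `true_ph`) and `standards` (data.frame: `ph`, `ratio` -- the
#'   noiseless model ratio at each clamped level).
#' @export
make_excitation_readings <- function(well_ph = population_ph_defaults(),
                                     standard_ph = seq(4.0, 6.0, by = 0.5),
                                     n_reads = 6, noise_sd = 0.01,
                                     f390_level = 100, seed = 1) {
  stop_if_not(length(standard_ph) >= 3,
              "need at least 3 calibration standards")
  with_seed(seed, {
    wells <- do.call(rbind, lapply(names(well_ph), function(w) {
      r <- excitation_ratio_model(well_ph[[w]])
      f390 <- f390_level * (1 + stats::rnorm(n_reads, 0, noise_sd))
      f340 <- f390_level * r * (1 + stats::rnorm(n_reads, 0, noise_sd))
      data.frame(well = w, read = seq_len(n_reads), f340 = f340,
                 f390 = f390, true_ph = well_ph[[w]],
                 stringsAsFactors = FALSE)
    }))
    standards <- data.frame(ph = standard_ph,
                            ratio = excitation_ratio_model(standard_ph))
    list(wells = wells, standards = standards)
  })
}
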