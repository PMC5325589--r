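# Single-lysosome and population pH pipelines.

toy_wl <- emission_wavelengths()

test_that("Weibull-5 fit recovers noiseless parameters and the peak identity", {
  truth <- list(y0 = 5, a = 100, x0 = 490, b = 60, c = 2.2)
  y <- weibull5(toy_wl, truth$y0, truth$a, truth$x0, truth$b, truth$c)
  fit <- fit_weibull5(toy_wl, y)
  expect_true(fit$converged)
  for (p in names(truth)) {
    expect_equal(fit[[p]], truth[[p]], tolerance = 1e-3)
  }
  # parameterization identity: fitted curve peaks at y0 + a at x0
  expect_equal(predict(fit, fit$x0), fit$y0 + fit$a, tolerance = 1e-12)
})

test_that("flat spectra and short spectra are rejected", {
  expect_error(fit_weibull5(toy_wl, rep(4, length(toy_wl))), "no peak")
  expect_error(fit_weibull5(420:424, c(1, 5, 9, 5, 1)), "at least 8")
})

test_that("fit matches a grid-refined least-squares oracle on toy spectra", {
  toys <- list(
    list(y0 = 5, a = 100, x0 = 490, b = 60, c = 2.2, noise = 0),
    list(y0 = 0, a = 50, x0 = 470, b = 40, c = 1.6, noise = 0),
    list(y0 = 20, a = 200, x0 = 520, b = 80, c = 3.0, noise = 0),
    list(y0 = 5, a = 100, x0 = 497, b = 60, c = 2.2, noise = 2),
    list(y0 = 10, a = 80, x0 = 480, b = 50, c = 2.0, noise = 1)
  )
  set.seed(99)
  for (tt in toys) {
    y <- weibull5(toy_wl, tt$y0, tt$a, tt$x0, tt$b, tt$c) +
      rnorm(length(toy_wl), 0, tt$noise)
    fit <- fit_weibull5(toy_wl, y)
    oracle_rss <- oracle_weibull5_rss(toy_wl, y)
    # fit must be at least as good as the oracle, up to 1% slack
    expect_lte(fit$rss, oracle_rss * 1.01 + 1e-9)
  }
})

test_that("emission ratio evaluates the fitted closed form at 470/524 nm", {
  y <- weibull5(toy_wl, 5, 100, 490, 60, 2.2)
  fit <- fit_weibull5(toy_wl, y)
  want <- weibull5(470, fit$y0, fit$a, fit$x0, fit$b, fit$c) /
    weibull5(524, fit$y0, fit$a, fit$x0, fit$b, fit$c)
  expect_equal(emission_ratio(fit), want)
  # baseline dominance: amplitude -> 0 drives the ratio to 1
  flatish <- structure(list(y0 = 100, a = 1e-9, x0 = 490, b = 60, c = 2.2,
                            rss = 0, converged = TRUE),
                       class = "weibull5_fit")
  expect_equal(emission_ratio(flatish), 1, tolerance = 1e-9)
})

test_that("linear calibration: exact collinear standards and OLS oracle", {
  cal <- fit_emission_calibration(ph = c(4.0, 4.5, 5.0, 5.5),
                                  ratio = c(2.4, 2.2, 2.0, 1.8))
  expect_equal(cal$slope, -0.4)
  expect_equal(cal$intercept, 4.0)
  expect_equal(cal$fit_r2, 1)
  expect_equal(cal$valid_ph_range, c(4.0, 5.5))

  # perturbed point: slope/intercept from the closed-form normal equations
  ph <- c(4.0, 4.5, 5.0, 5.5)
  ratio <- c(2.4, 2.25, 2.0, 1.8)
  cal2 <- fit_emission_calibration(ph = ph, ratio = ratio)
  sxx <- sum((ph - mean(ph))^2)
  slope <- sum((ph - mean(ph)) * (ratio - mean(ratio))) / sxx
  expect_equal(cal2$slope, slope)
  expect_equal(cal2$intercept, mean(ratio) - slope * mean(ph))

  expect_error(fit_emission_calibration(ph = c(4.5), ratio = c(2)),
               "underdetermined")
  expect_error(fit_emission_calibration(ph = c(4, 4.5, 5), ratio = c(2, 2, 2)),
               "not invertible")
  expect_error(fit_emission_calibration(ph = c(4, 4.5, 5, 5.5),
                                        ratio = c(2.4, 1.9, 2.0, 1.8)),
               "not invertible")
})

test_that("ratio_to_ph inverts the line, clamps out-of-range, idempotently", {
  cal <- fit_emission_calibration(ph = c(4.0, 4.5, 5.0, 5.5),
                                  ratio = c(2.4, 2.2, 2.0, 1.8))
  est <- ratio_to_ph(cal, 2.0)
  expect_equal(est$ph, 5.0)
  expect_false(est$clamped)
  # a ratio at a standard returns that standard's pH
  expect_equal(ratio_to_ph(cal, 2.2)$ph, 4.5)
  # ratio implying pH 6.3 clamps to the upper bound
  lo_ratio <- cal$intercept + cal$slope * 6.3
  est2 <- ratio_to_ph(cal, lo_ratio)
  expect_equal(est2$ph, 5.5)
  expect_true(est2$clamped)
  # idempotent: re-inverting the clamped value's ratio stays clamped at 5.5
  expect_equal(ratio_to_ph(cal, cal$intercept + cal$slope * 5.5)$ph, 5.5)
  # strictly monotone over the valid range
  rr <- seq(1.8, 2.4, by = 0.05)
  expect_true(all(diff(ratio_to_ph(cal, rr)$ph) < 0 |
                    diff(ratio_to_ph(cal, rr)$ph) == 0))
  expect_true(all(diff(ratio_to_ph(cal, rev(rr))$ph) >= 0))
})

test_that("ApoD classification thresholds ROI mean intensities", {
  img <- matrix(0, 10, 10)
  roi <- matrix(FALSE, 10, 10)
  roi[1:2, 1:2] <- TRUE
  expect_false(classify_apod(roi, img, 50))
  img[roi] <- 150
  expect_true(classify_apod(roi, img, 50))
  expect_error(classify_apod(matrix(FALSE, 10, 10), img, 50), "empty ROI")

  # 12 of 30 ROIs above threshold by construction
  set.seed(6)
  img2 <- matrix(0, 30, 10)
  rois <- lapply(1:30, function(i) {
    m <- matrix(FALSE, 30, 10)
    m[i, ] <- TRUE
    m
  })
  img2[1:12, ] <- 80
  flags <- classify_apod(rois, img2, 50)
  expect_equal(sum(flags), 12)
})

test_that("ph_distribution bins align at 4.0 and ties break low", {
  d <- ph_distribution(c(4.65, 4.72, 4.68, 4.41), bin_width = 0.1)
  expect_equal(d$modes$mode_center, 4.65)
  expect_equal(sort(d$histogram$count), c(1, 1, 2))
  # single record
  expect_equal(ph_distribution(4.7)$modes$mode_center, 4.75)
  # two equal-count bins: the lower-pH bin wins
  tie <- ph_distribution(c(4.41, 4.42, 4.61, 4.62))
  expect_equal(tie$modes$mode_center, 4.45)
})

test_that("ph_distribution groups by condition and class", {
  recs <- data.frame(ph = c(4.45, 4.46, 4.71, 4.72, 4.73),
                     class = c("ApoD-", "ApoD-", "ApoD+", "ApoD+", "ApoD+"),
                     condition = "control")
  d <- ph_distribution(recs)
  m <- d$modes
  expect_equal(m$mode_center[m$class == "ApoD-"], 4.45)
  expect_equal(m$mode_center[m$class == "ApoD+"], 4.75)
})

test_that("ApoD-positive fractions sum to one per condition", {
  recs <- data.frame(
    apod_positive = c(rep(TRUE, 12), rep(FALSE, 18), rep(TRUE, 30)),
    condition = c(rep("control", 30), rep("PQ2h", 30)))
  fr <- apod_lysosome_fractions(recs)
  expect_equal(fr$frac_positive[fr$condition == "control"], 0.4)
  expect_equal(fr$frac_negative[fr$condition == "control"], 0.6)
  expect_equal(fr$frac_positive[fr$condition == "PQ2h"], 1)
  expect_equal(fr$frac_positive + fr$frac_negative, c(1, 1))
})

test_that("excitation pipeline: interpolation arithmetic and clamping", {
  standards <- data.frame(ph = c(4.0, 4.5, 5.0, 5.5, 6.0),
                          ratio = c(2.4, 2.2, 2.0, 1.8, 1.6))
  # ratio exactly at a standard
  out <- population_ph_excitation(rep(220, 6), rep(100, 6), standards)
  expect_equal(out$ph, 4.5)
  # midway between standards
  out2 <- population_ph_excitation(rep(210, 6), rep(100, 6), standards)
  expect_equal(out2$ph, 4.75)
  # beyond the last standard: clamped
  out3 <- population_ph_excitation(rep(100, 6), rep(100, 6), standards)
  expect_equal(out3$ph, 6.0)
  expect_true(out3$clamped)
  expect_error(population_ph_excitation(rep(1, 6), rep(0, 6), standards),
               "zero F390")
  bad <- data.frame(ph = c(4, 4.5, 5), ratio = c(2, 1.5, 1.8))
  expect_error(population_ph_excitation(rep(1, 6), rep(1, 6), bad),
               "not invertible")
  expect_error(fit_excitation_calibration(ph = c(4, 5), ratio = c(2, 1)),
               "underdetermined")
})

test_that("noiseless closed loop recovers true pH to 1e-3", {
  gt <- spectrum_ground_truth(class = "ApoD+", noise_sd = 0, ph_sd = 0.3,
                              ph_mode = 4.8, n_lysosomes = 8, seed = 12)
  out <- make_spectra(gt)
  cal <- fit_emission_calibration(
    standards_to_ratios(make_calibration_standards(gt)))
  recs <- estimate_lysosome_ph(out$spectra, cal)
  truth <- out$truth$true_ph
  inside <- truth >= 4.0 & truth <= 5.5
  expect_true(any(inside))
  expect_lt(max(abs(recs$ph[inside] - truth[inside])), 1e-3)
  # values above the dynamic range clamp to its edge
  if (any(!inside)) {
    expect_true(all(recs$clamped[!inside]))
    expect_true(all(recs$ph[!inside] == 5.5))
  }
})

test_that("modal bin of the estimated pH matches the true draws' modal bin
          in at least 90% of seeded replicates", {
  hits <- vapply(1:50, function(s) {
    gt <- spectrum_ground_truth(class = "ApoD-", seed = 1000 + s)
    out <- make_spectra(gt)
    cal <- fit_emission_calibration(
      standards_to_ratios(make_calibration_standards(gt)))
    recs <- estimate_lysosome_ph(out$spectra, cal)
    est_mode <- ph_distribution(recs$ph)$modes$mode_center
    true_mode <- ph_distribution(out$truth$true_ph)$modes$mode_center
    abs(est_mode - true_mode) <= 0.1 + 1e-9
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
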