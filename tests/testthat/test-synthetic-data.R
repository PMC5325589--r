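# Generators: determinism, ground-truth bookkeeping, and the spectral
# model's structural guarantees.

test_that("vesicle scenes are deterministic and honor the coloc fraction", {
  spec <- vesicle_scene_spec(coloc_fraction = 0.5, seed = 11)
  s1 <- make_vesicle_scene(spec)
  s2 <- make_vesicle_scene(spec)
  expect_identical(s1$stack_a, s2$stack_a)
  expect_identical(s1$stack_b, s2$stack_b)
  expect_identical(s1$truth, s2$truth)

  for (frac in c(0, 0.3, 1)) {
    sc <- make_vesicle_scene(vesicle_scene_spec(coloc_fraction = frac,
                                                seed = 7))
    ta <- sc$truth[sc$truth$channel == "A", ]
    tb <- sc$truth[sc$truth$channel == "B", ]
    expect_equal(sum(ta$shared), round(frac * 30))
    expect_equal(sum(tb$shared), round(frac * 30))
    # shared vesicles occupy identical positions across channels
    if (any(ta$shared)) {
      expect_equal(ta[ta$shared, c("z", "y", "x")],
                   tb[tb$shared, c("z", "y", "x")],
                   ignore_attr = TRUE)
    }
  }
})

test_that("infeasible vesicle placement reports a placement failure", {
  expect_error(
    make_vesicle_scene(vesicle_scene_spec(shape = c(4, 8, 8),
                                          n_vesicles_a = 50,
                                          n_vesicles_b = 50, seed = 1)),
    "placement failure")
})

test_that("membrane ring adds channel-A signal only", {
  base <- make_vesicle_scene(vesicle_scene_spec(seed = 3, noise_sd = 0))
  ring <- make_vesicle_scene(vesicle_scene_spec(seed = 3, noise_sd = 0,
                                                membrane_ring = TRUE))
  expect_identical(base$stack_b, ring$stack_b)
  expect_true(sum(ring$stack_a) > sum(base$stack_a))
})

test_that("emission spectra follow the Weibull model with pH-shifted peak", {
  gt <- spectrum_ground_truth(noise_sd = 0, ph_sd = 0, ph_mode = 4.7,
                              n_lysosomes = 3, seed = 5)
  out <- make_spectra(gt)
  expect_equal(nrow(out$truth), 3)
  expect_true(all(out$truth$true_ph == 4.7))
  wl <- emission_wavelengths()
  s1 <- out$spectra[out$spectra$lysosome_id == 1, ]
  expect_equal(s1$wavelength_nm, wl)
  # noiseless spectra identical across lysosomes and equal to the model
  x0 <- emission_peak_position(4.7, gt)
  expect_equal(s1$intensity, weibull5(wl, 5, 100, x0, 60, 2.2))
  s2 <- out$spectra[out$spectra$lysosome_id == 2, ]
  expect_equal(s1$intensity, s2$intensity)
})

test_that("same seed reproduces spectra; true pH respects truncation", {
  gt <- spectrum_ground_truth(class = "ApoD+", condition = "PQ2h", seed = 9)
  a <- make_spectra(gt)
  b <- make_spectra(gt)
  expect_identical(a, b)
  expect_true(all(a$truth$true_ph >= 4.0 & a$truth$true_ph <= 6.0))
})

test_that("the 470/524 ratio of the spectral model is strictly monotone
          and linear in pH over the dynamic range", {
  gt <- spectrum_ground_truth(seed = 1)
  ph <- seq(4.0, 5.5, by = 0.1)
  x0 <- emission_peak_position(ph, gt)
  ratios <- vapply(x0, function(p) {
    f <- function(nm) weibull5(nm, gt$weibull_y0, gt$weibull_a, p,
                               gt$weibull_b, gt$weibull_c)
    f(470) / f(524)
  }, numeric(1))
  expect_true(all(diff(ratios) < 0))
  # linear by construction: second differences vanish
  expect_lt(max(abs(diff(diff(ratios)))), 1e-6)
  # nominal anchors: peak at 470 nm at pH 4.0, ~+18 nm/pH on average
  expect_equal(x0[1], 470, tolerance = 1e-6)
  expect_equal((x0[length(x0)] - x0[1]) / 1.5, 18, tolerance = 1e-6)
})

test_that("degenerate dye (zero peak slope) yields constant ratios", {
  gt <- spectrum_ground_truth(peak_map_slope = 0, peak_map_intercept = 470,
                              seed = 2)
  x0 <- emission_peak_position(c(4.0, 4.7, 5.5), gt)
  expect_true(all(x0 == 470))
  std <- make_calibration_standards(gt)
  ratios <- standards_to_ratios(std)
  expect_error(fit_emission_calibration(ratios), "not invertible")
})

test_that("calibration standards are noiseless replicas of the model", {
  gt <- spectrum_ground_truth(seed = 4)
  std <- make_calibration_standards(gt, ph_levels = c(4.0, 4.5, 5.0, 5.5))
  expect_equal(sort(unique(std$ph)), c(4.0, 4.5, 5.0, 5.5))
  s <- std[std$ph == 4.5, ]
  x0 <- emission_peak_position(4.5, gt)
  expect_equal(s$intensity, weibull5(s$wavelength_nm, 5, 100, x0, 60, 2.2))
  expect_error(make_calibration_standards(gt, ph_levels = numeric(0)),
               "non-empty")
  expect_error(make_calibration_standards(gt, ph_levels = c(3.0, 5.0)),
               "within")
})

test_that("lattice generator: spot counts, dropout bookkeeping, determinism", {
  lat <- make_lattice_image(lattice_spec(rows = 10, cols = 10,
                                         jitter_sd = 0, dropout_fraction = 0,
                                         seed = 1))
  expect_equal(nrow(lat$truth), 100)
  drop <- make_lattice_image(lattice_spec(rows = 10, cols = 10,
                                          dropout_fraction = 0.3, seed = 8))
  expect_lt(nrow(drop$truth), 100)
  # binomial survival around 70; generator records truth exactly
  expect_gt(nrow(drop$truth), 45)
  again <- make_lattice_image(lattice_spec(rows = 10, cols = 10,
                                           dropout_fraction = 0.3, seed = 8))
  expect_identical(drop, again)
})

test_that("particle fields record exact per-particle areas", {
  pf <- make_particle_field(particle_field_spec(n_particles = 5,
                                                radius_sd = 0, noise_sd = 0,
                                                seed = 2))
  expect_equal(nrow(pf$truth), 5)
  # all radii equal => all rasterized areas equal the single-disk area
  expect_equal(length(unique(pf$truth$area_px)), 1)
  expect_equal(sum(pf$image > 0), sum(pf$truth$area_px))
  empty <- make_particle_field(particle_field_spec(n_particles = 0, seed = 1))
  expect_equal(nrow(empty$truth), 0)
  expect_true(all(empty$image == 0))
})

test_that("excitation plate generator: ratios follow the dye model", {
  ex <- make_excitation_readings(noise_sd = 0, seed = 3)
  per_well <- tapply(ex$wells$f340 / ex$wells$f390, ex$wells$well, mean)
  truth <- population_ph_defaults()
  for (w in names(truth)) {
    expect_equal(unname(per_well[w]), excitation_ratio_model(truth[[w]]),
                 tolerance = 1e-12)
  }
  expect_true(all(diff(ex$standards$ratio) < 0))
})
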