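test_that("integrate_region handles flat, rectangular and Lorentzian signals", {
  ppm <- seq(0.5, 3.5, by = 0.002)
  zero <- spectrum1d("z", ppm, rep(0, length(ppm)))
  succ <- region_def("succ", 2.39, 2.43, 4L)
  expect_equal(integrate_region(zero, succ), 0)
  # unit-height rectangle spanning exactly the window: area = width
  rect <- spectrum1d("r", ppm, as.numeric(ppm >= 2.39 & ppm <= 2.43))
  expect_equal(integrate_region(rect, succ), 0.04, tolerance = 1e-10)
  # noise-free unit-area Lorentzian, FWHM 0.003 ppm at 2.41 (fine grid:
  # the lineshape is only a few points wide on the coarse one)
  ppm_f <- seq(2.3, 2.5, by = 1e-4)
  lor <- spectrum1d("l", ppm_f, {
    g <- 0.003 / 2
    (g / pi) / ((ppm_f - 2.41)^2 + g^2)
  })
  expect_equal(integrate_region(lor, succ),
               (2 / pi) * atan(2 * 0.02 / 0.003), tolerance = 1e-3)
})

test_that("linear baseline mode subtracts the endpoint chord", {
  ppm <- seq(2.3, 2.5, by = 0.001)
  ramp <- spectrum1d("ramp", ppm, 5 + 3 * ppm)  # pure linear background
  r <- region_def("succ", 2.39, 2.43)
  expect_gt(integrate_region(ramp, r, "none"), 0)
  expect_equal(integrate_region(ramp, r, "linear"), 0, tolerance = 1e-12)
})

test_that("calibration matches the closed-form window mass and is linear", {
  std <- make_reference_standard(grid = fast_grid(), noise_sd = 0)
  f <- calibrate(std)
  k_shape <- lactate_window_mass(1.5 / 500.13)
  expect_equal(f$area_per_proton_per_nmol, k_shape, tolerance = 1e-3)
  std2 <- std
  std2$spectrum$intensity <- 2 * std$spectrum$intensity
  expect_equal(calibrate(std2)$area_per_proton_per_nmol,
               2 * f$area_per_proton_per_nmol, tolerance = 1e-12)
  # quantifying the standard against itself returns the stated amount
  recovered <- integrate_region(std$spectrum, std$reference_region) /
    (std$reference_region$n_protons * f$area_per_proton_per_nmol)
  expect_equal(recovered, 19.3, tolerance = 1e-12)
  flat <- std
  flat$spectrum$intensity <- rep(0, length(flat$spectrum$intensity))
  expect_error(calibrate(flat), "calibration failed")
})

test_that("quantify_metabolite applies the formula, flags and errors", {
  std <- make_reference_standard(grid = fast_grid(), noise_sd = 0)
  f <- calibrate(std)
  succ <- region_def("succinate", 2.39, 2.43, 4L)
  ppm <- seq(fast_grid()$ppm_min, fast_grid()$ppm_max, by = fast_grid()$step)
  zero <- spectrum1d("z", ppm, rep(0, length(ppm)), weight_mg = 15)
  qz <- quantify_metabolite(zero, succ, f)
  expect_equal(qz$concentration, 0)
  expect_true(qz$below_detection)
  # high-SNR synthetic sample recovers the SDHx median within 5%
  tr <- make_truth(succinate = 3.6, weight_mg = 15)
  s <- render_spectrum(tr, grid = fast_grid(), noise_sd = 0.01, seed = 2)
  q <- quantify_metabolite(s, succ, f)
  expect_false(q$below_detection)
  expect_lt(abs(q$concentration - 3.6) / 3.6, 0.05)
  # doubling the weight at fixed spectrum halves the concentration
  s2 <- s; s2$weight_mg <- 30
  q2 <- quantify_metabolite(s2, succ, f)
  expect_equal(q2$concentration, q$concentration / 2, tolerance = 1e-12)
  s_nw <- spectrum1d("nw", ppm, s$intensity)
  expect_error(quantify_metabolite(s_nw, succ, f), "weight")
})

test_that("reported concentration is linear in true concentration", {
  std <- make_reference_standard(grid = fast_grid(), noise_sd = 0)
  f <- calibrate(std)
  succ <- region_def("succinate", 2.39, 2.43, 4L)
  concs <- c(0.5, 1, 2, 4)
  est <- vapply(concs, function(cc) {
    s <- render_spectrum(make_truth(succinate = cc), grid = fast_grid(),
                         noise_sd = 0)
    quantify_metabolite(s, succ, f, apply_detection = FALSE)$concentration
  }, numeric(1))
  slope <- coef(lm(est ~ concs))[["concs"]]
  expect_lt(abs(slope - 1), 0.02)
})

test_that("in-window intensity increases never decrease the concentration", {
  std <- make_reference_standard(grid = fast_grid(), noise_sd = 0)
  f <- calibrate(std)
  succ <- region_def("succinate", 2.39, 2.43, 4L)
  s <- render_spectrum(make_truth(succinate = 1), grid = fast_grid(),
                       noise_sd = 0)
  base <- quantify_metabolite(s, succ, f, apply_detection = FALSE)$concentration
  for (bump_at in c(2.395, 2.41, 2.425)) {
    s2 <- s
    s2$intensity <- s2$intensity + 10 * exp(-((s2$ppm - bump_at) / 0.002)^2)
    expect_gte(quantify_metabolite(s2, succ, f,
                                   apply_detection = FALSE)$concentration,
               base)
  }
})

test_that("detection limit separates signal from pure noise", {
  g <- default_grid()
  ppm <- seq(g$ppm_min, g$ppm_max, by = g$step)
  r <- region_def("probe", 2.39, 2.43)
  # zero-noise positive peak is always above detection
  s <- render_spectrum(make_truth(succinate = 0.01), grid = g, noise_sd = 0)
  expect_true(detect_limit(s, r))
  # pure-noise windows fall below the 3-sigma rule (Gaussian tail)
  below <- vapply(1:20, function(i) {
    set.seed(i)
    sn <- spectrum1d("n", ppm, rnorm(length(ppm)), weight_mg = 15)
    !detect_limit(sn, r)
  }, logical(1))
  expect_gte(sum(below), 19)
})

test_that("catecholamine subtraction recovers the VHL-like pattern", {
  std <- make_reference_standard(grid = default_grid(), noise_sd = 0)
  f <- calibrate(std)
  panel <- panel_defaults()
  # epinephrine absent, norepinephrine 1.8 nmol/mg (the VHL median)
  s_vhl <- render_spectrum(make_truth(norepinephrine = 1.8, group = "VHL"),
                           grid = default_grid(), noise_sd = 0.5, seed = 4)
  q <- quantify_catecholamines(s_vhl, panel, f)
  expect_true(q$epinephrine_below)
  expect_equal(q$epinephrine, 0)
  expect_lt(abs(q$norepinephrine - 1.8) / 1.8, 0.1)
  expect_false(q$dopamine_flag)
  # pure epinephrine: aromatic total is consumed by E, NE clips to ~0
  s_epi <- render_spectrum(make_truth(epinephrine = 1.5),
                           grid = default_grid(), noise_sd = 0.2, seed = 5)
  q2 <- suppressWarnings(quantify_catecholamines(s_epi, panel, f))
  expect_lt(q2$norepinephrine, 0.15)
  expect_lt(abs(q2$epinephrine - 1.5) / 1.5, 0.1)
  # dopamine present: both triplet positions light up
  s_dopa <- render_spectrum(make_truth(dopamine = 1.0),
                            grid = default_grid(), noise_sd = 0.2, seed = 6)
  q3 <- quantify_catecholamines(s_dopa, panel, f)
  expect_true(q3$dopamine_flag)
})

test_that("detection decisions reproduce generator epinephrine presence", {
  sim <- simulate_cohort(small_cohort(seed = 17L))
  q <- quantify_cohort(sim$spectra, sim$standard)
  agree <- (sim$truth$epinephrine > 0) == (q$quant$epinephrine > 0)
  expect_gte(mean(agree), 0.95)
})

test_that("quantify_cohort returns the cohort feature matrix", {
  sim <- simulate_cohort(small_cohort(seed = 1L))
  q <- quantify_cohort(sim$spectra, sim$standard)
  expect_equal(dim(q$features), c(28, 4))
  expect_equal(colnames(q$features),
               c("succinate", "glutathione", "glutamate", "atp_adp_amp"))
  expect_length(q$failures, 0)
  expect_true(all(q$quant$succinate >= 0))
  # empty cohort: empty table, no error
  q0 <- quantify_cohort(list(), sim$standard)
  expect_equal(nrow(q0$quant), 0)
  # failures are collected without aborting the run
  bad <- sim$spectra
  bad[[3]]$weight_mg <- NULL
  qb <- quantify_cohort(bad, sim$standard)
  expect_equal(nrow(qb$quant), 27)
  expect_length(qb$failures, 1)
})

test_that("median recovered SDHx succinate stays near the generator median", {
  meds <- vapply(1:3, function(seed) {
    sim <- simulate_cohort(small_cohort(seed = seed))
    q <- quantify_cohort(sim$spectra, sim$standard)
    median(q$quant$succinate[q$quant$group == "SDHx"])
  }, numeric(1))
  true_meds <- vapply(1:3, function(seed) {
    median(simulate_cohort(small_cohort(seed = seed))$truth$succinate[
      simulate_cohort(small_cohort(seed = seed))$truth$group == "SDHx"])
  }, numeric(1))
  expect_lt(abs(median(meds) - median(true_meds)) / median(true_meds), 0.1)
})

test_that("total-integral feature scaling yields relative features", {
  sim <- simulate_cohort(cohort_spec(n = c(sporadic = 2L, SDHx = 2L, VHL = 2L),
                                     seed = 5L))
  q <- quantify_cohort(sim$spectra, sim$standard,
                       feature_scaling = "total_integral")
  expect_true(all(q$features >= 0 & q$features <= 1))
  expect_equal(colnames(q$features),
               c("succinate", "glutathione", "glutamate", "atp_adp_amp"))
})
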