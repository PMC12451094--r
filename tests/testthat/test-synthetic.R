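test_that("generator is exact in the noiseless limit and seed-deterministic", {
  cfg <- scenario_config(pH = 2, analyte = "anthocyanin", model = "decay",
                         params = list(C0 = 24, k = 1.44), noise_sd = 0,
                         prep_cv = 0, seed = 5)
  ser <- gen_kinetic_series(cfg)
  expect_length(ser, cfg$n_prep * cfg$n_meas)
  for (s in ser)
    expect_equal(s$value, 24 * exp(-1.44 * s$day), tolerance = 1e-12)

  cfg2 <- scenario_config(pH = 3, analyte = "LOOH", model = "sigmoid",
                          params = list(c0 = 29, cmax = 2172, k = 1.6),
                          seed = 77)
  a <- gen_kinetic_series(cfg2)
  b <- gen_kinetic_series(cfg2)
  expect_identical(a, b)
  cfg3 <- scenario_config(pH = 3, analyte = "LOOH", model = "sigmoid",
                          params = list(c0 = 29, cmax = 2172, k = 1.6),
                          seed = 78)
  expect_false(identical(gen_kinetic_series(cfg3), a))
})

test_that("noisy decay scenarios are recovered by fitting within 10%", {
  # pooled replicate fit per seed; median recovered k across seeds near truth
  ks <- vapply(1:40, function(s) {
    cfg <- scenario_config(pH = 2, analyte = "anthocyanin", model = "decay",
                           params = list(C0 = 24, k = 1.44),
                           noise_sd = 0.05 * 24, seed = s)
    ser <- gen_kinetic_series(cfg)
    df <- do.call(rbind, lapply(ser, as.data.frame))
    unname(coef(fit_decay(df))["k"])
  }, 0)
  expect_lt(abs(median(ks) - 1.44) / 1.44, 0.10)
})

test_that("synthetic spectra place the pigment band per the pH anchors", {
  s2 <- gen_spectrum(2, with_sds = FALSE, day = 0, seed = 1)
  s6 <- gen_spectrum(6, with_sds = FALSE, day = 0, seed = 2)
  expect_lt(abs(lambda_max(s2) - 522), 1)
  expect_lt(abs(lambda_max(s6) - 546), 2)
  # amplitude falls to ~0.41 of the pH 2 level at pH 6 (turbidity-corrected)
  r <- turbidity_correct(s6, peak_nm = 546) / turbidity_correct(s2, peak_nm = 522)
  expect_equal(r, 0.41, tolerance = 0.03)
  expect_error(gen_spectrum(7), "pH")
  expect_identical(gen_spectrum(3, seed = 4)$absorbance,
                   gen_spectrum(3, seed = 4)$absorbance)
})

test_that("surfactant adjustments propagate through spectral_shift", {
  sh <- spectral_shift(gen_spectrum(2, FALSE, seed = 10),
                       gen_spectrum(2, TRUE, seed = 11))
  expect_equal(sh$delta_nm, 8, tolerance = 1)
  expect_identical(sh$kind, "bathochromic")
  expect_equal(sh$rel_abs_change, 20, tolerance = 1.5)
  sh6 <- spectral_shift(gen_spectrum(6, FALSE, seed = 12),
                        gen_spectrum(6, TRUE, seed = 13))
  expect_equal(sh6$delta_nm, -6, tolerance = 1)
  expect_identical(sh6$kind, "hypsochromic")
})

test_that("stored spectra decay with the pH-specific pigment rate", {
  a0 <- turbidity_correct(gen_spectrum(2, day = 0, seed = 3, noise_sd = 0))
  a1 <- turbidity_correct(gen_spectrum(2, day = 1, seed = 3, noise_sd = 0))
  expect_equal(a1 / a0, exp(-1.44), tolerance = 0.01)
})

test_that("presets cover the study conditions with the reported rates", {
  pr <- kinetic_presets()
  expect_true(all(c("pH2_anthocyanin", "pH3_LOOH", "pH3_LOOH_extract",
                    "pH6_hexanal_extract") %in% names(pr)))
  expect_equal(pr$pH2_anthocyanin$params$k, 1.44)
  expect_equal(pr$pH4_anthocyanin$params$k, 0.06)
  expect_equal(pr$pH3_LOOH$params$cmax, 2172)
  ks <- vapply(paste0("pH", c(2, 3, 4, 6), "_anthocyanin"),
               function(nm) pr[[nm]]$params$k, 0)
  expect_true(ks[1] > ks[2] && ks[2] > ks[4] && ks[4] > ks[3])
  # distinct seeds per preset, all reproducible from the base seed
  seeds <- vapply(pr, function(p) p$seed, 0L)
  expect_false(any(duplicated(seeds)))
  expect_identical(seeds, vapply(kinetic_presets(), function(p) p$seed, 0L))
})

test_that("scenario_config validates its inputs", {
  expect_error(scenario_config(2, "LOOH", "sigmoid",
                               params = list(c0 = 10, cmax = 5, k = 1)),
               "cmax")
  expect_error(scenario_config(2, "anthocyanin", "decay",
                               params = list(C0 = 24, k = 1), noise_sd = -1),
               "noise_sd")
  expect_error(scenario_config(2, "anthocyanin", "decay",
                               params = list(k = 1)), "C0")
})
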