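wl1 <- seq(380, 780, by = 1)

test_that("turbidity correction subtracts the scattering baseline", {
  a <- 0.05 + 1.2 * exp(-0.5 * ((wl1 - 522) / 40)^2)
  sp <- absorbance_spectrum(wl1, a)
  expect_equal(turbidity_correct(sp), 1.2, tolerance = 1e-6)
  flat <- absorbance_spectrum(wl1, rep(0.3, length(wl1)))
  expect_equal(turbidity_correct(flat), 0)
  # stronger signal at 750 nm than at the peak flags a scattering artifact
  rising <- absorbance_spectrum(wl1, 0.001 * (wl1 - 380))
  expect_warning(v <- turbidity_correct(rising), "artifact")
  expect_lt(v, 0)
  narrow <- absorbance_spectrum(seq(400, 700, 1), rep(0.1, 301))
  expect_error(turbidity_correct(narrow), "covers")
})

test_that("lambda_max locates band maxima with sub-grid refinement", {
  for (center in c(522, 546)) {
    sp <- absorbance_spectrum(wl1, exp(-0.5 * ((wl1 - center) / 40)^2))
    expect_lt(abs(lambda_max(sp) - center), 0.5)
  }
  # off-grid center recovered by parabolic interpolation
  sp <- absorbance_spectrum(wl1, exp(-0.5 * ((wl1 - 523.4) / 40)^2))
  expect_lt(abs(lambda_max(sp) - 523.4), 0.2)
  # two equal peaks: tie broken towards the lower wavelength
  two <- exp(-0.5 * ((wl1 - 500) / 10)^2) + exp(-0.5 * ((wl1 - 540) / 10)^2)
  expect_lt(lambda_max(absorbance_spectrum(wl1, two)), 510)
  expect_error(lambda_max(absorbance_spectrum(wl1, two), window = c(450, 451)),
               "5 grid points")
})

test_that("spectral_shift reproduces the surfactant worked examples", {
  gauss <- function(center, amp) amp * exp(-0.5 * ((wl1 - center) / 40)^2)
  # bathochromic +8 nm with 20% hyperchromic gain (1.0 -> 1.25)
  sh <- spectral_shift(absorbance_spectrum(wl1, gauss(522, 1.0)),
                       absorbance_spectrum(wl1, gauss(530, 1.25)))
  expect_equal(sh$delta_nm, 8, tolerance = 0.2)
  expect_identical(sh$kind, "bathochromic")
  expect_equal(sh$rel_abs_change, 20, tolerance = 0.2)
  # hypsochromic -6 nm at nearly constant intensity
  sh2 <- spectral_shift(absorbance_spectrum(wl1, gauss(546, 0.41)),
                        absorbance_spectrum(wl1, gauss(540, 0.42)))
  expect_equal(sh2$delta_nm, -6, tolerance = 0.2)
  expect_identical(sh2$kind, "hypsochromic")
  expect_lt(abs(sh2$rel_abs_change), 3)
  # identity
  sp <- absorbance_spectrum(wl1, gauss(530, 1))
  sh3 <- spectral_shift(sp, sp)
  expect_identical(sh3$kind, "none")
  expect_equal(sh3$delta_nm, 0)
  expect_equal(sh3$rel_abs_change, 0)
})

test_that("a perfectly transparent sample maps to the white point", {
  lab <- spectrum_to_lab(absorbance_spectrum(wl1, rep(0, length(wl1))))
  expect_equal(lab$L, 100, tolerance = 0.05)
  expect_lt(abs(lab$a), 0.05)
  expect_lt(abs(lab$b), 0.05)
  expect_true(lab$hue_undefined)
})

test_that("uniform absorbance gives the closed-form grey lightness", {
  lab <- spectrum_to_lab(absorbance_spectrum(wl1, rep(2, length(wl1))))
  # T = 0.01 everywhere -> Y/Yn = 0.01 -> L* = 116 * 0.01^(1/3) - 16
  expect_equal(lab$L, 116 * 0.01^(1/3) - 16, tolerance = 1e-6)
  expect_lt(abs(lab$a), 1e-6)
  expect_lt(abs(lab$b), 1e-6)
})

test_that("the shipped CIE tables reproduce the illuminant C white point", {
  w <- attr(cie_tables(), "white")
  xy <- w / sum(w)
  expect_lt(abs(xy["X"] - 0.31006), 0.002)
  expect_lt(abs(xy["Y"] - 0.31616), 0.002)
  tab <- cie_tables()
  expect_true(all(tab$xbar >= 0 & tab$ybar >= 0 &
                  tab$zbar >= 0 & tab$illuminant >= 0))
})

test_that("a green-absorbing band looks red-magenta, matching an independent integrator", {
  A <- 1.2 * exp(-0.5 * ((wl1 - 530) / 40)^2)
  lab <- spectrum_to_lab(absorbance_spectrum(wl1, A))
  expect_true(lab$h_deg > 300 || lab$h_deg < 30)
  expect_gt(lab$a, 0)
  ora <- oracle_lab(wl1, A)
  expect_lt(abs(lab$L - ora["L"]), 0.5)
  expect_lt(abs(lab$a - ora["a"]), 0.5)
  expect_lt(abs(lab$b - ora["b"]), 0.5)
})

test_that("pointwise larger absorbance gives lower lightness", {
  base <- 0.3 * exp(-0.5 * ((wl1 - 520) / 60)^2)
  Ls <- vapply(c(0.5, 1, 1.5, 2, 3), function(s)
    spectrum_to_lab(absorbance_spectrum(wl1, s * base))$L, 0)
  expect_true(all(diff(Ls) < 0))
})

test_that("spectrum_to_lab rejects spectra with large coverage gaps", {
  expect_error(spectrum_to_lab(absorbance_spectrum(seq(420, 780, 1),
                                                   rep(0.1, 361))), "gap")
  # a <=10 nm end gap is tolerated by edge extension
  lab <- spectrum_to_lab(absorbance_spectrum(seq(388, 775, 1), rep(0, 388)))
  expect_equal(lab$L, 100, tolerance = 0.05)
})

test_that("CIEDE2000 matches the published verification pairs", {
  pairs <- list(
    list(c(50, 2.6772, -79.7751), c(50, 0, -82.7485), 2.0425),
    list(c(50, 3.1571, -77.2803), c(50, 0, -82.7485), 2.8615),
    list(c(50, 2.8361, -74.0200), c(50, 0, -82.7485), 3.4412),
    list(c(50, 0, 0), c(50, -1, 2), 2.3669),
    list(c(50, 2.49, -0.001), c(50, -2.49, 0.0009), 7.1792),
    list(c(50, 2.49, -0.001), c(50, -2.49, 0.0010), 7.1792))
  for (p in pairs) {
    expect_equal(delta_e2000(p[[1]], p[[2]]), p[[3]], tolerance = 1e-4)
    expect_equal(delta_e2000(p[[2]], p[[1]]), p[[3]], tolerance = 1e-4)
  }
})

test_that("CIEDE2000 agrees with an independent implementation on random colours", {
  skip_if_not_installed("farver")
  set.seed(19)
  n <- 200
  m1 <- cbind(runif(n, 0, 100), runif(n, -80, 80), runif(n, -80, 80))
  m2 <- cbind(runif(n, 0, 100), runif(n, -80, 80), runif(n, -80, 80))
  mine <- vapply(seq_len(n), function(i) delta_e2000(m1[i, ], m2[i, ]), 0)
  ref <- diag(farver::compare_colour(m1, m2, from_space = "lab",
                                     method = "cie2000"))
  expect_lt(max(abs(mine - ref)), 1e-4)
})

test_that("CIEDE2000 is a symmetric premetric", {
  set.seed(23)
  for (i in 1:100) {
    l1 <- c(runif(1, 0, 100), runif(1, -80, 80), runif(1, -80, 80))
    l2 <- c(runif(1, 0, 100), runif(1, -80, 80), runif(1, -80, 80))
    d12 <- delta_e2000(l1, l2)
    expect_gte(d12, 0)
    expect_equal(d12, delta_e2000(l2, l1), tolerance = 1e-12)
  }
  expect_identical(delta_e2000(c(50, 10, -10), c(50, 10, -10)), 0)
})

test_that("complete pigment fade spans a large colour difference", {
  # day-0 red emulsion vs day-7 faded emulsion (L,a,b as reported at pH 2)
  d <- delta_e2000(lab_color(53, 46, 25), lab_color(90, -0.3, 21))
  expect_gt(d, 30)
  expect_error(delta_e2000(lab_color(50, 0, 0, illuminant = "C"),
                           lab_color(50, 0, 0, illuminant = "D65")),
               "illuminant")
})

test_that("lab_color derives chroma and hue consistently", {
  lc <- lab_color(50, 3, -4)
  expect_equal(lc$C, 5)
  expect_equal(lc$h_deg, (atan2(-4, 3) * 180 / pi) %% 360)
  expect_true(lc$h_deg >= 0 && lc$h_deg < 360)
  expect_true(lab_color(50, 0, 0)$hue_undefined)
})
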