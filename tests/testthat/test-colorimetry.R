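test_that("observer tables load, resample at knots, and reject unknown names", {
  cmfs <- load_observer("cie1931_2deg")
  expect_equal(dim(cmfs$M), c(61, 3))
  expect_true(all(cmfs$M >= 0))
  # linear interpolation is exact at shared samples of a coarser grid
  coarse <- load_observer("cie1931_2deg", wl_grid(400, 700, 10))
  shared <- match(coarse$grid$wl, cmfs$grid$wl)
  expect_equal(coarse$M, cmfs$M[shared, ], ignore_attr = TRUE)
  expect_error(load_observer("cie1964_10deg"), "arg")
  # cone observer is the fixed linear transform of the CIE table
  lms <- load_observer("hpe_lms")
  expect_equal(lms$M[17, ], drop(cmfs$M[17, , drop = FALSE] %*%
                                 t(huecancel:::hpe_matrix())),
               ignore_attr = TRUE)
})

test_that("spectral integration is linear and yields equal-energy chromaticity", {
  cmfs <- load_observer("cie1931_2deg")
  g <- cmfs$grid
  expect_equal(as.numeric(spectrum_to_tristimulus(flat_spectrum(g, 0), cmfs)),
               c(0, 0, 0))
  s1 <- quasi_mono(g, 480, 1, 5, 0)
  s2 <- quasi_mono(g, 600, 2, 8, 0.1)
  t_sum <- spectrum_to_tristimulus(spd(g, s1$radiance + s2$radiance), cmfs)
  expect_equal(as.numeric(t_sum),
               as.numeric(spectrum_to_tristimulus(s1, cmfs)) +
                 as.numeric(spectrum_to_tristimulus(s2, cmfs)),
               tolerance = 1e-12)
  # the equienergetic point: only grid truncation moves it off (1/3, 1/3)
  w <- chromaticity_of(spectrum_to_tristimulus(flat_spectrum(g, 1), cmfs))
  expect_equal(w, c(1 / 3, 1 / 3), tolerance = 0.01)
})

test_that("chromaticity projection normalizes and is scale invariant", {
  expect_equal(chromaticity_of(tristim(c(1, 1, 1))), c(1 / 3, 1 / 3))
  expect_equal(chromaticity_of(tristim(c(2, 1, 1))), c(0.5, 0.25))
  set.seed(5)
  v <- stats::runif(3, 0.1, 2)
  expect_equal(chromaticity_of(tristim(v)), chromaticity_of(tristim(7.3 * v)))
  expect_error(chromaticity_of(tristim(c(1, -2, 0.5))), "positive")
})

test_that("complements reproduce the white and match a brute-force oracle", {
  cmfs <- load_observer("cie1931_2deg")
  white <- chromaticity_of(spectrum_to_tristimulus(flat_spectrum(cmfs$grid, 1), cmfs))

  # defining property: the mixture at the returned ratio is the white
  locus <- spectral_locus(cmfs)
  for (l in seq(410, 690, by = 20)) {
    cr <- complementary_wavelength(l, white, cmfs)
    cq <- huecancel:::locus_chromaticity(l, locus)
    mix <- cr$mixing_ratio * huecancel:::lift_chromaticity(cq) +
      (1 - cr$mixing_ratio) * huecancel:::lift_chromaticity(cr$chromaticity)
    expect_equal(chromaticity_of(tristim(mix)), white, tolerance = 1e-6)
  }

  # against the independent locus-walking oracle
  for (l in c(440, 475, 530, 610)) {
    cr <- complementary_wavelength(l, white, cmfs)
    bf <- brute_force_complement(l, white, cmfs)
    expect_equal(cr$kind, bf$kind)
    if (cr$kind == "spectral")
      expect_equal(cr$wavelength_nm, bf$wavelength_nm, tolerance = 0.2)
    else
      expect_equal(cr$chromaticity, bf$chromaticity, tolerance = 1e-3,
                   ignore_attr = TRUE)
  }
  expect_equal(complementary_wavelength(475, white, cmfs)$kind, "spectral")
  expect_gt(complementary_wavelength(475, white, cmfs)$wavelength_nm, 560)
  expect_equal(complementary_wavelength(530, white, cmfs)$kind, "purple")
  expect_error(complementary_wavelength(530, huecancel:::locus_chromaticity(530, locus), cmfs),
               "undefined|white")
})

test_that("spectral complementation is an involution on the spectral subset", {
  cmfs <- load_observer("cie1931_2deg")
  white <- chromaticity_of(spectrum_to_tristimulus(flat_spectrum(cmfs$grid, 1), cmfs))
  for (l in c(430, 450, 470, 480)) {
    c1 <- complementary_wavelength(l, white, cmfs)
    expect_equal(c1$kind, "spectral")
    c2 <- complementary_wavelength(c1$wavelength_nm, white, cmfs)
    expect_equal(c2$kind, "spectral")
    expect_equal(c2$wavelength_nm, l, tolerance = 0.5)
  }
})

test_that("space conversions are consistent, linear, and annihilate the white in ATD", {
  cmfs <- load_observer("cie1931_2deg")
  white <- spectrum_to_tristimulus(flat_spectrum(cmfs$grid, 1), cmfs)
  params <- space_params(as.numeric(white))

  atd_w <- to_space(white, "atd", params)
  expect_equal(as.numeric(atd_w)[2:3], c(0, 0), tolerance = 1e-12)
  expect_equal(as.numeric(atd_w)[1], 1)
  # A channel is all-positive, T and D opponent in spectral sensitivity
  atd_sens <- cmfs$M %*% t(params$atd)
  expect_true(all(atd_sens[, 1] >= 0))
  expect_true(min(atd_sens[, 2]) < 0 && max(atd_sens[, 2]) > 0)
  expect_true(min(atd_sens[, 3]) < 0 && max(atd_sens[, 3]) > 0)

  t0 <- tristim(c(30, 45, 20))
  for (sp in c("lms", "atd", "rgb_linear")) {
    round_trip <- to_space(to_space(t0, sp, params), "xyz", params)
    expect_equal(as.numeric(round_trip), as.numeric(t0), tolerance = 1e-10)
    a <- 2.7
    expect_equal(as.numeric(to_space(tristim(a * as.numeric(t0)), sp, params)),
                 a * as.numeric(to_space(t0, sp, params)), tolerance = 1e-10)
  }

  # degenerate display nonlinearity: gamma = 1 leaves only the fixed scaling
  params1 <- space_params(as.numeric(white), gamma_display = 1)
  dig <- to_space(t0, "rgb_digital", params1)
  lin <- to_space(t0, "rgb_linear", params1)
  expect_equal(as.numeric(dig), as.numeric(lin) * params1$digital_scale,
               tolerance = 1e-12)
  expect_error(to_space(t0, "ycbcr", params), "unknown")
})

test_that("physical spectra stay inside the spectral-locus + purple-line hull", {
  cmfs <- load_observer("cie1931_2deg")
  locus <- spectral_locus(cmfs)
  poly <- locus[, 2:3]   # closed implicitly by the purple line
  set.seed(42)
  for (k in 1:25) {
    r <- stats::runif(61, 0, 1) * stats::rbinom(61, 1, 0.7)
    if (sum(r) == 0) r[30] <- 1
    cc <- chromaticity_of(spectrum_to_tristimulus(spd(cmfs$grid, r), cmfs))
    # shrink marginally toward the white to avoid boundary ties
    w <- c(1 / 3, 1 / 3)
    expect_true(point_in_polygon(w + (cc - w) * (1 - 1e-9), poly))
  }
})

test_that("reference valence curves cross zero where their CMF combinations do", {
  ref <- jh_reference_valences()
  cmfs <- load_observer("cie1931_2deg")
  expect_true(all(is.finite(c(ref$rg, ref$yb))))
  expect_length(ref$rg, 61)
  expect_equal(ref$rg, drop(cmfs$M %*% c(1, -1, 0)))
  expect_equal(ref$yb, drop(cmfs$M %*% c(0, 0.4, -0.4)))
  # a user-supplied digitized file takes precedence
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  utils::write.csv(data.frame(wavelength_nm = seq(400, 700, 5),
                              rg = ref$rg * 2, yb = ref$yb * 2),
                   path, row.names = FALSE)
  ref2 <- jh_reference_valences(file = path)
  expect_equal(ref2$rg, ref$rg * 2, tolerance = 1e-9)
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(nm = 1:3, v = 1:3), bad, row.names = FALSE)
  expect_error(jh_reference_valences(file = bad), "columns")
  unlink(bad)
})
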