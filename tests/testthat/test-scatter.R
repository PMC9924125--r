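test_that("equivalent square side preserves cross-sectional area", {
  s <- equivalent_square_side(c(0.158, 0.352))
  expect_equal(s^2, pi * c(0.158, 0.352)^2 / 4)
  expect_equal(equivalent_square_side(0), 0)
  expect_error(equivalent_square_side(-0.1), "nonnegative")
})

test_that("foam lateral spread reduces to its closed-form limits", {
  # no foam scattering: pure drift of the incident angular spread
  p <- scatter_params(0.03, 0, foam_thickness = 1.27)
  expect_equal(sigma_x_foam(p), 0.03 * 1.27)
  # no incident spread: Fermi-Eyges foam growth term alone
  p2 <- scatter_params(0, 0.5, foam_density = 0.096, foam_thickness = 1.27)
  expect_equal(sigma_x_foam(p2), 1.27 * sqrt(0.5 * 0.096 * 1.27 / 6))
  expect_equal(sigma_x_foam(scatter_params(0, 0)), 0)
})

test_that("in-scatter fraction is monotone with the right limits", {
  s <- equivalent_square_side(0.273)
  sx <- seq(0.005, 0.5, by = 0.005)
  f <- inscatter_fraction(s, sx)
  expect_true(all(diff(f) > 0))          # increasing in sigma_x
  expect_true(all(f >= 0 & f < 1))
  ss <- seq(0.05, 0.5, by = 0.01)
  expect_true(all(diff(inscatter_fraction(ss, 0.04)) < 0))  # decreasing in s
  expect_identical(inscatter_fraction(s, 0), 0)
  expect_lt(inscatter_fraction(s, 1e-9), 1e-8)
  expect_gt(inscatter_fraction(s, 50), 0.999)  # sigma_x -> Inf limit f -> 1
  expect_error(inscatter_fraction(0, 0.04), "positive")
})

test_that("one calibrated spread per energy reproduces the published f table", {
  tab <- study_inscatter_table()
  for (lab in unique(tab$energy_label)) {
    rows <- tab[tab$energy_label == lab, ]
    ref <- rows[rows$d_nom == 0.158, ]
    sx <- calibrate_sigma_x(equivalent_square_side(0.158), ref$f)
    f_pred <- inscatter_fraction(equivalent_square_side(rows$d_nom), sx)
    expect_true(all(abs(f_pred - rows$f) <= 0.001), info = lab)
  }
})

test_that("spread calibration inverts the in-scatter fraction", {
  s <- equivalent_square_side(0.158)
  for (f in c(0.05, 0.172, 0.420, 0.9)) {
    sx <- calibrate_sigma_x(s, f)
    expect_equal(inscatter_fraction(s, sx), f, tolerance = 1e-9)
  }
  expect_equal(calibrate_sigma_x(s, 0.420), 0.0419, tolerance = 2e-3)
  expect_equal(calibrate_sigma_x(s, 0.172), 0.0158, tolerance = 2e-3)
  expect_error(calibrate_sigma_x(s, 1.2), "0, 1")
  expect_error(calibrate_sigma_x(s, 0), "0, 1")
})

test_that("effective-diameter and IRF adjustments are mutually consistent", {
  expect_equal(round(d_in_scatter(0.158, 0.420), 3), 0.188)
  expect_equal(round(d_in_scatter(0.352, 0.125), 3), 0.373)
  expect_identical(d_in_scatter(0.3, 0), 0.3)
  expect_equal(round(irf_in_scatter(0.937, 0.420), 3), 0.911)
  expect_equal(round(irf_in_scatter(0.688, 0.202), 3), 0.625)
  expect_identical(irf_in_scatter(0.8, 0), 0.8)
  # removing the same fractional fluence two ways gives identical IRFs
  for (d in c(0.1, 0.273, 0.352)) {
    for (f in c(0, 0.1, 0.42)) {
      expect_equal(irf_nominal(d_in_scatter(d, f), 0.6),
                   irf_in_scatter(irf_nominal(d, 0.6), f),
                   tolerance = 1e-12)
    }
  }
  expect_error(d_in_scatter(0.2, 1), "\\[0, 1\\)")
  expect_error(irf_in_scatter(1.2, 0.1), "\\(0, 1\\]")
})

test_that("modified-diameter surface evaluates, warns, and degenerates correctly", {
  expect_equal(d_modified(0.158, 20.47), 0.1557, tolerance = 2e-4)
  expect_equal(d_modified(0.352, 13.12), 0.3535, tolerance = 2e-4)
  ident <- dmod_coefficients(0, 1, 0, 0, 0, 0)
  expect_equal(d_modified(c(0.2, 0.3), 13, ident), c(0.2, 0.3))
  expect_warning(d_modified(0.2, 25), "extrapolat")
  expect_error(d_modified(0, 13), "positive")
})

test_that("surface fitting recovers exact quadratics and rejects bad input", {
  true <- dmod_coefficients(0.02, 1.1, -0.003, -0.2, -0.001, 5e-5)
  pts <- expand.grid(d_nom = c(0.15, 0.25, 0.35), e_p0 = c(7, 13, 20))
  pts$d_mod <- d_modified(pts$d_nom, pts$e_p0, true)
  fit <- fit_dmod_surface(pts)
  expect_equal(unclass(fit), unclass(true), tolerance = 1e-10)
  expect_error(fit_dmod_surface(pts[1:5, ]), "at least 6")
  one_d <- data.frame(d_nom = 0.2, e_p0 = c(7, 9, 11, 13, 15, 17), d_mod = 0.2)
  expect_error(fit_dmod_surface(one_d), "span")
})

test_that("refitting the study calibration points leaves small residuals", {
  tab <- study_dmod_table()
  fit <- fit_dmod_surface(tab)
  pred <- d_modified(tab$d_nom, tab$e_p0, fit)
  expect_true(all(abs(pred - tab$d_mod) <= 0.002))
})
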