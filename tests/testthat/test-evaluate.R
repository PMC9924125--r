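make_grid <- function(values, y = seq(-2, 2, 0.1), z = seq(0.1, 2.5, 0.1)) {
  if (is.function(values)) values <- outer(y, z, values)
  dose_grid(y, z, values)
}

test_that("RMS agrees with a direct-sum oracle", {
  reg <- region_spec(y_half_width = 1.5, z_min = 0.5, z_max = 2)
  base <- make_grid(function(y, z) 80 - 5 * z + 0.1 * y)
  expect_equal(rms_percent(base, base, reg), 0)
  offset <- make_grid(base$values + 1)
  expect_equal(rms_percent(offset, base, reg), 1)
  set.seed(3)
  noisy <- make_grid(base$values + matrix(rnorm(length(base$values)),
                                          nrow(base$values)))
  iy <- abs(base$y) <= 1.5 + 1e-9
  iz <- base$z >= 0.5 - 1e-9 & base$z <= 2 + 1e-9
  acc <- 0; n <- 0
  for (i in which(iy)) for (j in which(iz)) {
    acc <- acc + (noisy$values[i, j] - base$values[i, j])^2; n <- n + 1
  }
  expect_equal(rms_percent(noisy, base, reg), sqrt(acc / n))
  coarse <- make_grid(function(y, z) 80 - 5 * z + 0.1 * y, y = seq(-2, 2, 0.2))
  expect_error(rms_percent(base, coarse, reg), "coordinates")
  expect_error(rms_percent(base, base, region_spec(z_min = 5, z_max = 6)),
               "no grid points")
})

test_that("pass rate handles the flat-field dose-only limits", {
  reg <- region_spec(y_half_width = 1.5, z_min = 0.5, z_max = 2)
  flat <- make_grid(function(y, z) rep(80, length(y)))
  expect_equal(pass_rate_2pct_2mm(flat, flat, reg)$pass_rate, 100)
  up21 <- make_grid(flat$values + 2.1)
  expect_equal(pass_rate_2pct_2mm(up21, flat, reg)$pass_rate, 0)
  up19 <- make_grid(flat$values + 1.9)
  expect_equal(pass_rate_2pct_2mm(up19, flat, reg)$pass_rate, 100)
  expect_error(pass_rate_2pct_2mm(flat, flat, reg, dta_tol = 0.05),
               "too coarse")
})

test_that("distance to agreement rescues a shifted gradient", {
  reg <- region_spec(y_half_width = 1.5, z_min = 0.5, z_max = 2)
  # 20%/cm depth gradient shifted by 1.5 mm: 3% dose difference everywhere,
  # but the calculated distribution attains the measured value 1.5 mm away.
  meas <- make_grid(function(y, z) 100 - 20 * z)
  calc <- make_grid(function(y, z) 100 - 20 * (z - 0.15))
  rep <- pass_rate_2pct_2mm(calc, meas, reg)
  expect_equal(rep$pass_rate, 100)
  # shifting beyond the DTA tolerance fails everywhere in the flat direction
  calc_far <- make_grid(function(y, z) 100 - 20 * (z - 0.30))
  expect_equal(pass_rate_2pct_2mm(calc_far, meas, reg)$pass_rate, 0)
})

test_that("pass rate is monotone in error inflation and in the tolerances", {
  reg <- region_spec(y_half_width = 1.5, z_min = 0.5, z_max = 2)
  meas <- make_grid(function(y, z) 90 - 10 * z + 2 * sin(3 * y))
  set.seed(11)
  err <- matrix(rnorm(length(meas$values), 0, 1.5), nrow(meas$values))
  rates <- sapply(c(0.5, 1, 2, 4), function(scale) {
    pass_rate_2pct_2mm(make_grid(meas$values + scale * err), meas, reg)$pass_rate
  })
  expect_true(all(diff(rates) <= 0))
  calc <- make_grid(meas$values + 2 * err)
  by_dose <- sapply(c(1, 2, 4), function(tol) {
    pass_rate_2pct_2mm(calc, meas, reg, dose_tol = tol)$pass_rate
  })
  expect_true(all(diff(by_dose) >= 0))
  by_dta <- sapply(c(0.2, 0.4), function(tol) {
    pass_rate_2pct_2mm(calc, meas, reg, dta_tol = tol)$pass_rate
  })
  expect_true(all(diff(by_dta) >= 0))
})

test_that("pass rate and RMS rank inversely across perturbed grids", {
  reg <- region_spec(y_half_width = 1.5, z_min = 0.5, z_max = 2)
  meas <- make_grid(function(y, z) 90 - 10 * z + 2 * sin(3 * y))
  # smooth systematic error: DTA cannot rescue it everywhere, so the pass
  # rate degrades as the error scale (and hence the RMS) grows
  err <- outer(cos(0.6 * meas$y), rep(1, length(meas$z)))
  stats <- t(sapply(c(0.5, 1.5, 2.2, 2.6, 3.5), function(scale) {
    rep <- pass_rate_2pct_2mm(make_grid(meas$values + scale * err), meas, reg)
    c(rep$pass_rate, rep$rms_percent)
  }))
  expect_true(all(diff(stats[, 1]) <= 0))
  expect_true(all(diff(stats[, 2]) > 0))
  expect_lt(cor(stats[, 1], stats[, 2], method = "spearman"), 0)
})

test_that("diameter calibration is self-consistent on exact forward data", {
  dev <- fixture_device()
  beam <- study_beams("7MeV")
  reg <- default_regions("7MeV")
  meas <- fixture_meas(d_true = 0.273)
  d_hat <- optimize_dmod(meas, dev, beam, reg, bounds = c(0.24, 0.31))
  expect_equal(as.numeric(d_hat), 0.273, tolerance = 2e-3)
  # optimized diameter does not increase the region RMS over nominal
  y <- meas$y[abs(meas$y) <= reg$y_half_width + 1e-9]
  z <- meas$z[meas$z >= reg$z_min - 1e-9 & meas$z <= reg$z_max + 1e-9]
  sub <- function(g) dose_grid(y, z, g$values[match(y, g$y), match(z, g$z)])
  calc_opt <- calc_dose_grid(dev, beam, y, z, d_override = as.numeric(d_hat))
  calc_nom <- calc_dose_grid(dev, beam, y, z, d_override = 0.26)
  m <- sub(meas)
  expect_lte(rms_percent(calc_opt, m, reg), rms_percent(calc_nom, m, reg))
  expect_error(optimize_dmod(meas, dev, beam, reg, bounds = c(0.4, 0.3)),
               "interval")
})
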