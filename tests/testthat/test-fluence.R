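test_that("blurred step has the right symmetry, sharp limit, and area", {
  expect_equal(blurred_step(0, 0.2, 0.05),
               2 * pnorm(sqrt(2) * 0.2 / (sqrt(2) * 0.05)) - 1)
  expect_identical(blurred_step(0, 0.2, 0), 1)
  expect_identical(blurred_step(c(-0.3, 0.3), 0.2, 0), c(0, 0))
  # convolution conserves area for every sigma (midpoint quadrature)
  u <- seq(-3, 3, by = 0.001) + 5e-4
  for (sig in c(0, 0.02, 0.1, 0.4)) {
    area <- sum(blurred_step(u, 0.25, sig)) * 0.001
    expect_equal(area, 0.5, tolerance = 1e-3, info = paste("sigma", sig))
  }
})

test_that("block shadows are translation-equivariant and additive", {
  x <- seq(-2, 2, by = 0.05); y <- x
  d1 <- prime_device(data.frame(x = 0, y = 0, d = 0.3))
  d2 <- prime_device(data.frame(x = 0.8, y = -0.4, d = 0.3))
  f1 <- device_fluence(d1, 0.06, x, y)$values
  f2 <- device_fluence(d2, 0.06, x + 0.8, y - 0.4)$values
  expect_equal(f1, f2, tolerance = 1e-12)
  both <- prime_device(data.frame(x = c(0, 0.8), y = c(0, -0.4), d = 0.3),
                       r = 0.6)
  fb <- device_fluence(both, 0.06, x, y)$values
  f2h <- device_fluence(d2, 0.06, x, y)$values
  expect_equal(1 - fb, (1 - f1) + (1 - f2h), tolerance = 1e-12)
})

test_that("a sharp single block casts a full central shadow", {
  dev <- prime_device(data.frame(x = 0, y = 0, d = 0.352))
  fm <- device_fluence(dev, 0.005, seq(-1, 1, 0.05), seq(-1, 1, 0.05))
  ctr <- which(fm$x == 0)
  expect_lt(fm$values[ctr, ctr], 1e-6)
  expect_equal(max(fm$values), 1, tolerance = 1e-9)
})

test_that("integrated fluence deficit equals the equivalent-square area", {
  d <- 0.352; s <- equivalent_square_side(d)
  dev <- prime_device(data.frame(x = 0, y = 0, d = d))
  for (sig in c(0.01, 0.05, 0.2)) {
    h <- 0.005; ext <- s / 2 + 8 * sig + 0.2
    x <- seq(-ext, ext, by = h)
    deficit <- sum(1 - device_fluence(dev, sig, x, x)$values) * h^2
    expect_equal(deficit, s^2, tolerance = 1e-3, info = paste("sigma", sig))
  }
})

test_that("modified diameters shrink the deficit at 20 MeV and grow it at 7 MeV", {
  dev <- fixture_device(0.273)
  x <- seq(-4.5, 4.5, by = 0.1)
  deficit <- function(fm) sum(1 - fm$values)
  nom <- deficit(device_fluence(dev, 0.1, x, x))
  lo <- deficit(device_fluence(dev, 0.1, x, x, diameter_mode = "modified",
                               e_p0 = 7.14))
  hi <- deficit(device_fluence(dev, 0.1, x, x, diameter_mode = "modified",
                               e_p0 = 20.47))
  expect_gt(lo, nom)
  expect_lt(hi, nom)
})

test_that("dose composition multiplies PDD and off-axis ratio", {
  beam <- study_beams("7MeV")
  pdd <- gen_pdd(beam)
  y <- seq(-2, 2, by = 0.1); z <- seq(0.1, 3, by = 0.1)
  unit <- compose_dose(pdd, function(y, z) rep(1, length(y)), y, z)
  expect_equal(unit$values, matrix(rep(pdd(z), each = length(y)), length(y)))
  flat <- compose_dose(function(z) rep(80, length(z)),
                       function(y, z) rep(0.812, length(y)), y, z)
  expect_equal(unique(as.vector(flat$values)), 64.96)
  expect_error(compose_dose(pdd, function(y, z) rep(1, length(y)),
                            y, c(1, 50)), "PDD domain")
})

test_that("foam-only forward dose is normalised to 100 on the central axis", {
  beam <- study_beams("13MeV")
  foam <- prime_device(NULL)
  g <- calc_dose_grid(foam, beam, seq(-6, 6, 0.1), seq(0.1, beam$rp, 0.1))
  cax <- g$values[which(abs(g$y) < 1e-9), ]
  expect_equal(max(cax), 100, tolerance = 1e-6)
  # monotone falloff beyond r100 on the central axis
  fall <- cax[g$z >= beam$r100]
  expect_true(all(diff(fall) <= 1e-9))
})

test_that("dose-grid CSV round trip is stable", {
  g <- dose_grid(seq(-1, 1, 0.5), seq(0.1, 0.5, 0.1),
                 matrix(runif(25) * 100, 5, 5))
  p <- withr::local_tempfile(fileext = ".csv")
  write_dose_grid(g, p)
  g2 <- read_dose_grid(p)
  expect_equal(g2$y, g$y)
  expect_equal(g2$z, g$z)
  expect_equal(g2$values, g$values, tolerance = 1e-8)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_dose_grid(g2, p2)
  expect_identical(readLines(p), readLines(p2))
})
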