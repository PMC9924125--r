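# Shared fixtures and independent oracles used across test files.

# Brute-force hexagonal lattice site count: double loop over row / column
# indices, independent of the vectorised builder.
brute_hex_count <- function(extent_x, extent_y, r, tol = 1e-9) {
  dy <- sqrt(3) / 2 * r
  n <- 0
  for (k in -200:200) {
    y <- k * dy
    if (abs(y) > extent_y / 2 + tol) next
    off <- if (k %% 2 == 0) 0 else 0.5
    for (m in -200:200) {
      x <- (m + off) * r
      if (abs(x) <= extent_x / 2 + tol) n <- n + 1
    }
  }
  n
}

# Monte-Carlo oracle for the in-scatter fraction: launch points uniform
# on the equivalent square, independent Gaussian lateral displacements,
# score 1 - (1-D retained fraction)^2.  Returns the estimate and its
# delta-method standard error.
mc_inscatter <- function(s, sigma_x, n = 1e6, seed = 42) {
  set.seed(seed)
  u0 <- runif(n, -s / 2, s / 2)
  p <- mean(abs(u0 + rnorm(n, 0, sigma_x)) <= s / 2)
  list(f = 1 - p^2, se = 2 * p * sqrt(p * (1 - p) / n))
}

# Small fast forward-model setup shared by calibration tests.
fixture_device <- function(d_nom = 0.273) build_hex_device(8.4, 8.4, 0.6, d_nom)

# A dose grid restricted to the 7 MeV modulated region (small => fast).
fixture_meas <- function(d_true, noise_sd = 0, seed = 1) {
  gen_measured_grid(synthetic_config(study_beams("7MeV"), fixture_device(),
                                     d_true = d_true, noise_sd = noise_sd,
                                     seed = seed, y_extent = 4.5))
}
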