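#' Analytic percent-depth-dose stand-in
#'
#' Piecewise-smooth curve through a beam's depth-dose landmarks: a cosine
#' build-up ramp from `surface_pct` at the surface to exactly 100 at
#' `r100`; a shaped cosine falloff from 100 to the x-ray background at
#' `rp`, with its exponent solved so the curve passes exactly through 90
#' at `r90`; constant background beyond `rp`.  This is a stand-in with
#' the right landmarks and monotone falloff, not a claim about the true
#' shape of any clinical beam's depth dose.
#'
#' @param beam a [beam_spec()].
#' @param surface_pct surface dose, percent (default 85, typical of
#'   clinical electron beams).
#' @return function of depth z (cm, vectorised) returning percent dose;
#'   `NA` outside `[0, 3 * rp]`.
#' @export
gen_pdd <- function(beam, surface_pct = 85) {
  stopifnot(inherits(beam, "beam_spec"), surface_pct > 0, surface_pct < 100)
  r100 <- beam$r100; r90 <- beam$r90; rp <- beam$rp
  bg <- beam$x_ray_background
  if (bg >= 90) stop("x-ray background must be below 90%")
  u90 <- (r90 - r100) / (rp - r100)
  t90 <- (90 - bg) / (100 - bg)
  # falloff shape g(u) = (1 + cos(pi u^p))/2 with g(u90) = t90 exactly
  p <- log(acos(2 * t90 - 1) / pi) / log(u90)
  function(z) {
    out <- rep(NA_real_, length(z))
    ok <- z >= 0 & z <= 3 * rp
    zb <- z[ok]
    v <- numeric(length(zb))
    up <- zb <= r100
    v[up] <- surface_pct + (100 - surface_pct) *
      (1 - cos(pi * zb[up] / r100)) / 2
    mid <- zb > r100 & zb <= rp
    u <- (zb[mid] - r100) / (rp - r100)
    v[mid] <- bg + (100 - bg) * (1 + cos(pi * u^p)) / 2
    v[zb > rp] <- bg
    out[ok] <- v
    out
  }
}

#' Configuration of a synthetic measured dose grid
#'
#' @param beam a [beam_spec()].
#' @param device a [prime_device()].
#' @param d_true ground-truth effective block diameter, cm (insert
#'   plane), in (0, r).
#' @param noise_sd measurement noise SD, percent of given dose.
#' @param seed integer RNG seed.
#' @param spacing grid spacing, cm.
#' @param y_extent lateral half-extent of the grid, cm.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(beam, device, d_true, noise_sd = 0, seed = 1,
                             spacing = 0.1, y_extent = 6) {
  stopifnot(inherits(beam, "beam_spec"), inherits(device, "prime_device"),
            noise_sd >= 0, spacing > 0, y_extent > 0)
  if (!(d_true > 0 && d_true < device$r)) stop("d_true must be in (0, r)")
  structure(list(beam = beam, device = device, d_true = d_true,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 spacing = spacing, y_extent = y_extent),
            class = "synthetic_config")
}

#' Generate a synthetic "measured" water-phantom dose grid
#'
#' Samples the forward model ([calc_dose_grid()]) at the ground-truth
#' effective diameter on the regular measurement grid and adds
#' independent homoscedastic Gaussian noise (percent of given dose,
#' seeded and reproducible).  Emulates the structure of scanned
#' water-phantom data (PDD times off-axis profiles regridded to 0.1 cm),
#' so the diameter-calibration loop can be exercised without
#' measurements.  Ground truth and seed are recorded as attributes.
#'
#' @param cfg a [synthetic_config()].
#' @param ... forwarded to [calc_dose_grid()].
#' @return a [dose_grid()] with attributes `d_true` and `seed`.
#' @export
gen_measured_grid <- function(cfg, ...) {
  stopifnot(inherits(cfg, "synthetic_config"))
  y <- seq(-cfg$y_extent, cfg$y_extent, by = cfg$spacing)
  z <- seq(cfg$spacing, cfg$beam$rp, by = cfg$spacing)
  grid <- calc_dose_grid(cfg$device, cfg$beam, y, z,
                         d_override = cfg$d_true, ...)
  if (cfg$noise_sd > 0) {
    set.seed(cfg$seed)
    grid$values <- pmax(grid$values +
      matrix(stats::rnorm(length(grid$values), 0, cfg$noise_sd),
             nrow(grid$values)), 0)
  }
  attr(grid, "d_true") <- cfg$d_true
  attr(grid, "seed") <- cfg$seed
  grid
}

#' Write the four study device files
#'
#' Writes the foam-only device and the three 247-block hexagonal test
#' devices (nominal diameters 0.158, 0.273 and 0.352 cm on the standard
#' 8.4 x 8.4 cm^2, 0.6 cm-pitch lattice) in the device file dialect of
#' [write_device_file()].
#'
#' @param dir output directory (created if missing).
#' @return invisible character vector of the four file paths.
#' @export
gen_test_device_files <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  diam <- c(0.158, 0.273, 0.352)
  paths <- file.path(dir, c("device_foam_only.txt",
                            sprintf("device_d%04.0f.txt", 1000 * diam)))
  write_device_file(prime_device(NULL), paths[1])
  for (i in seq_along(diam)) {
    write_device_file(build_hex_device(8.4, 8.4, 0.6, diam[i]), paths[i + 1])
  }
  invisible(paths)
}
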