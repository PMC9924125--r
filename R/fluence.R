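#' Relative planar fluence map
#'
#' @param x,y coordinate vectors, cm (uniform grids; x cross-plane, y
#'   in-plane).
#' @param values matrix of relative planar fluence, dim
#'   `c(length(x), length(y))`; open field = 1.
#' @return object of class `fluence_map`.
#' @export
fluence_map <- function(x, y, values) {
  stopifnot(is.matrix(values), nrow(values) == length(x),
            ncol(values) == length(y))
  check_uniform <- function(v, nm) {
    if (length(v) > 1 && diff(range(diff(v))) > 1e-9) {
      stop(nm, " grid must be uniform")
    }
  }
  check_uniform(x, "x"); check_uniform(y, "y")
  structure(list(x = x, y = y, values = values), class = "fluence_map")
}

#' 2-D dose grid in percent of given dose
#'
#' Lateral (in-plane y) by depth (z) matrix of percent dose, with 100 =
#' central-axis maximum for the foam-only device.
#'
#' @param y lateral coordinates, cm (uniform grid).
#' @param z depth coordinates, cm (uniform grid, 0.1 cm default spacing).
#' @param values matrix, dim `c(length(y), length(z))`, percent dose.
#' @return object of class `dose_grid`.
#' @export
dose_grid <- function(y, z, values) {
  stopifnot(is.matrix(values), nrow(values) == length(y),
            ncol(values) == length(z))
  if (any(values < -1e-9)) stop("dose values must be nonnegative")
  structure(list(y = y, z = z, values = values), class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("Dose grid: %d y x %d z points, y in [%g, %g] cm, z in [%g, %g] cm\n",
              length(x$y), length(x$z), min(x$y), max(x$y), min(x$z), max(x$z)))
  cat(sprintf("  dose range %.2f-%.2f %% of given dose\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.fluence_map <- function(x, ...) {
  cat(sprintf("Fluence map: %d x %d points, transmission range %.4f-%.4f\n",
              length(x$x), length(x$y), min(x$values), max(x$values)))
  invisible(x)
}

#' Gaussian-blurred top-hat profile
#'
#' 1-D convolution of an indicator of half-width `half_width` with a
#' zero-mean Gaussian of RMS `sigma`:
#' \deqn{H(u) = \tfrac12 [\mathrm{erf}((u+a)/\sqrt{2}\sigma)
#'   - \mathrm{erf}((u-a)/\sqrt{2}\sigma)].}
#' `sigma = 0` returns the sharp indicator.  The integral over u is
#' `2 * half_width` for every sigma (convolution conserves area), which is
#' what makes the block-shadow fluence deficit independent of blur.
#'
#' @param u evaluation offsets, cm (vectorised).
#' @param half_width a, cm (> 0).
#' @param sigma Gaussian RMS, cm (>= 0).
#' @return dimensionless profile in \[0, 1\].
#' @export
blurred_step <- function(u, half_width, sigma) {
  stopifnot(half_width > 0, sigma >= 0)
  if (sigma == 0) return(as.numeric(abs(u) <= half_width))
  0.5 * (erf((u + half_width) / (sqrt(2) * sigma)) -
           erf((u - half_width) / (sqrt(2) * sigma)))
}

# Mode-selected per-block diameters at the insert plane.
block_diameters <- function(device, diameter_mode = c("nominal", "in_scatter",
                                                      "modified"),
                            e_p0 = NULL, sigma_x = NULL,
                            coeffs = dmod_coefficients()) {
  diameter_mode <- match.arg(diameter_mode)
  d <- device$blocks$d
  if (length(d) == 0) return(d)
  switch(diameter_mode,
    nominal = d,
    in_scatter = {
      if (is.null(sigma_x)) stop("diameter_mode='in_scatter' needs sigma_x")
      f <- inscatter_fraction(equivalent_square_side(d), sigma_x)
      d_in_scatter(d, f)
    },
    modified = {
      if (is.null(e_p0)) stop("diameter_mode='modified' needs e_p0")
      d_modified(d, e_p0, coeffs)
    }
  )
}

# Fluence transmission on an (x, y) grid: open field minus one blurred
# equivalent-square shadow per block.  Blocks whose shadow cannot reach
# the evaluation window (beyond max(s)/2 + 8 sigma) are skipped.
fluence_values <- function(xb, yb, s, x, y, sigma,
                           field_half_width = Inf, sigma_edge = 0.3) {
  open_x <- if (is.infinite(field_half_width)) rep(1, length(x)) else
    blurred_step(x, field_half_width, sigma_edge)
  open_y <- if (is.infinite(field_half_width)) rep(1, length(y)) else
    blurred_step(y, field_half_width, sigma_edge)
  phi <- outer(open_x, open_y)
  if (length(xb) > 0) {
    reach <- max(s) / 2 + 8 * max(sigma, 1e-12)
    keep <- xb >= min(x) - reach & xb <= max(x) + reach &
            yb >= min(y) - reach & yb <= max(y) + reach
    for (i in which(keep)) {
      hx <- blurred_step(x - xb[i], s[i] / 2, sigma)
      hy <- blurred_step(y - yb[i], s[i] / 2, sigma)
      phi <- phi - outer(hx, hy)
    }
    if (sigma == 0 && length(xb) > 1) {
      dmin <- min(stats::dist(cbind(xb, yb)))
      if (dmin < max(s) - 1e-12) {
        warning("overlapping square footprints at sigma = 0; local deficit may exceed 1")
      }
    }
  }
  phi
}

#' Planar fluence under a PRIME device
#'
#' Forward fluence model: the open-field fluence (1 inside the field, with
#' an erf-blurred penumbra of RMS `sigma_edge` when `field_half_width` is
#' finite) minus, for each island block, a Gaussian-blurred square shadow
#' of side equal to the block's equivalent square
#' ([equivalent_square_side()]) centred on the block, all blurred with the
#' same RMS `sigma`.  The integrated deficit of each shadow equals its
#' square area for every sigma, so the spatial mean transmission under a
#' periodic lattice equals the IRF for the mode-selected diameter.
#'
#' Coordinates are interpreted in the same plane as the device's block
#' coordinates; no divergence projection is applied here (see
#' [calc_dose_grid()] for the projected dose model).
#'
#' @param device a [prime_device()].
#' @param sigma Gaussian blur RMS, cm.
#' @param x,y evaluation grids, cm.
#' @param diameter_mode which effective diameter the shadows use:
#'   `"nominal"` (physical), `"in_scatter"` (pencil-beam theory, needs
#'   `sigma_x`) or `"modified"` (calibrated surface, needs `e_p0`).
#' @param e_p0,sigma_x,coeffs parameters for the non-nominal modes.
#' @param field_half_width half-size of the open field, cm (Inf = broad
#'   beam).
#' @param sigma_edge penumbra RMS of the open-field edge, cm.
#' @return a [fluence_map()].
#' @export
device_fluence <- function(device, sigma, x, y,
                           diameter_mode = "nominal", e_p0 = NULL,
                           sigma_x = NULL, coeffs = dmod_coefficients(),
                           field_half_width = Inf, sigma_edge = 0.3) {
  stopifnot(inherits(device, "prime_device"), sigma >= 0)
  d <- block_diameters(device, diameter_mode, e_p0, sigma_x, coeffs)
  s <- equivalent_square_side(d)
  phi <- fluence_values(device$blocks$x, device$blocks$y, s, x, y, sigma,
                        field_half_width, sigma_edge)
  fluence_map(x, y, phi)
}

#' Depth-dependent lateral spread in water
#'
#' Power-law stand-in for the growth of pencil-beam RMS width with depth,
#' \deqn{\sigma_w(z) = k\, z^{3/2} / \sqrt{E_{p,0}},}
#' mimicking Fermi-Eyges growth (faster than linear in depth, weaker at
#' high energy).  The constant k is configurable; the default 0.3
#' cm^{-1/2} MeV^{1/2} gives spreads of a few mm at shallow depths rising
#' to ~1 cm near the practical range, typical of clinical electron beams.
#'
#' @param z depth, cm (vectorised).
#' @param e_p0 beam energy, MeV.
#' @param k growth constant.
#' @return sigma_w, cm.
#' @export
sigma_water <- function(z, e_p0, k = 0.3) {
  stopifnot(e_p0 > 0, k >= 0)
  k * z^1.5 / sqrt(e_p0)
}

#' Compose a dose grid from a depth-dose curve and off-axis ratios
#'
#' `D(y, z) = PDD(z) * OAR(y, z)`: central-axis percent depth dose times
#' the off-axis ratio, reconstructing the 2-D in-plane dose matrix the
#' way scanned water-phantom data are combined.  Any x-ray background is
#' part of the PDD, not added here.
#'
#' @param pdd function of depth (cm) returning percent dose, e.g. from
#'   [gen_pdd()].
#' @param oar matrix of off-axis ratios, dim `c(length(y), length(z))`,
#'   or a function `(y, z)` evaluated on the grid.
#' @param y,z output grid, cm.
#' @return a [dose_grid()].
#' @export
compose_dose <- function(pdd, oar, y, z) {
  stopifnot(is.function(pdd))
  if (is.function(oar)) {
    oar <- outer(y, z, oar)
  }
  stopifnot(is.matrix(oar), nrow(oar) == length(y), ncol(oar) == length(z))
  pz <- pdd(z)
  if (any(!is.finite(pz))) stop("depth outside the PDD domain")
  dose_grid(y, z, sweep(oar, 2, pz, `*`))
}

#' Forward dose model under a PRIME device
#'
#' Single-redefinition Gaussian pencil-beam transport: blocks (insert
#' plane) are projected to the phantom plane by divergent-beam scaling,
#' each depth's off-axis fluence profile at x = 0 is computed with blur
#' \eqn{\sigma(z)^2 = \sigma_{device}^2 + \sigma_w(z)^2}, and multiplied
#' by the central-axis PDD.  This is a deliberately simple stand-in for a
#' full pencil-beam redefinition dose engine; it shares its structure
#' (effective-diameter block shadows subtracted from an open field) but
#' performs one redefinition at the phantom surface only.
#'
#' @param device a [prime_device()] (insert-plane coordinates).
#' @param beam a [beam_spec()].
#' @param y,z output grid, cm (phantom plane / depth).
#' @param d_override optional scalar diameter (insert plane, cm) applied
#'   to every block, bypassing `diameter_mode` — used by the calibration
#'   optimizer.
#' @param diameter_mode,sigma_x,coeffs see [device_fluence()];
#'   `sigma_x` defaults to the calibrated per-energy table for
#'   `"in_scatter"` mode.
#' @param pdd depth-dose function; defaults to the analytic stand-in
#'   [gen_pdd()] for `beam`.
#' @param sigma_device shadow blur at the surface, cm; default
#'   [default_sigma_device()].
#' @param k_water growth constant of [sigma_water()].
#' @param field_half_width,sigma_edge open-field model at the phantom
#'   plane, cm.
#' @return a [dose_grid()], normalised so the foam-only device has a
#'   central-axis maximum of 100.
#' @export
calc_dose_grid <- function(device, beam, y, z, d_override = NULL,
                           diameter_mode = "nominal", sigma_x = NULL,
                           coeffs = dmod_coefficients(), pdd = NULL,
                           sigma_device = NULL, k_water = 0.3,
                           field_half_width = 10.5, sigma_edge = 0.3) {
  stopifnot(inherits(device, "prime_device"), inherits(beam, "beam_spec"))
  if (is.null(pdd)) pdd <- gen_pdd(beam)
  if (is.null(sigma_device)) sigma_device <- default_sigma_device(beam$e_p0)
  if (is.null(sigma_x) && identical(diameter_mode, "in_scatter")) {
    sx <- calibrated_sigma_x_table()
    ep <- c("7MeV" = 7.14, "13MeV" = 13.12, "20MeV" = 20.47)
    sigma_x <- unname(sx[names(ep)[which.min(abs(ep - beam$e_p0))]])
  }
  d <- if (!is.null(d_override)) {
    rep(d_override, nrow(device$blocks))
  } else {
    block_diameters(device, diameter_mode, beam$e_p0, sigma_x, coeffs)
  }
  # project block geometry from the insert plane to the phantom plane
  plane_from <- device$source_to_isocenter - device$insert_to_isocenter
  plane_to <- beam$ssd
  xb <- project_between_planes(device$blocks$x, plane_from, plane_to)
  yb <- project_between_planes(device$blocks$y, plane_from, plane_to)
  s <- equivalent_square_side(project_between_planes(d, plane_from, plane_to))
  pz <- pdd(z)
  if (any(!is.finite(pz))) stop("depth outside the PDD domain")
  vals <- matrix(0, length(y), length(z))
  for (j in seq_along(z)) {
    sig <- sqrt(sigma_device^2 + sigma_water(z[j], beam$e_p0, k_water)^2)
    phi <- fluence_values(xb, yb, s, 0, y, sig, field_half_width, sigma_edge)
    vals[, j] <- pz[j] * phi[1, ]
  }
  dose_grid(y, z, pmax(vals, 0))
}

#' Write a dose grid (or fluence map) to CSV
#'
#' Wide layout: header row `y` followed by the depth coordinates; each
#' subsequent row is a lateral coordinate followed by the dose values at
#' that y across depths.  Values are written with 9 significant digits so
#' a read/write round trip is stable.
#'
#' @param grid a [dose_grid()].
#' @param path output file.
#' @export
write_dose_grid <- function(grid, path) {
  stopifnot(inherits(grid, "dose_grid"))
  fmt <- function(v) formatC(v, digits = 9, format = "g")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("y", fmt(grid$z)), collapse = ","), con)
  for (i in seq_along(grid$y)) {
    writeLines(paste(c(fmt(grid$y[i]), fmt(grid$values[i, ])),
                     collapse = ","), con)
  }
  invisible(path)
}

#' Read a dose grid written by [write_dose_grid()]
#'
#' @param path CSV file.
#' @return a [dose_grid()].
#' @export
read_dose_grid <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("dose grid file has no data rows")
  z <- as.numeric(strsplit(lines[1], ",")[[1]][-1])
  body <- do.call(rbind, lapply(strsplit(lines[-1], ","), as.numeric))
  if (any(is.na(body)) || any(is.na(z))) stop("malformed dose grid CSV")
  dose_grid(body[, 1], z, body[, -1, drop = FALSE])
}
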