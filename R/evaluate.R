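#' Evaluation region (modulated region) specification
#'
#' The region the calibration and agreement metrics operate on: within
#' `y_half_width` of central axis and between `z_min` and `z_max` in
#' depth (0.5 cm to slightly beyond R90 for the study beams).
#'
#' @param y_half_width cm.
#' @param z_min,z_max cm.
#' @return object of class `region_spec`.
#' @export
region_spec <- function(y_half_width = 3.5, z_min = 0.5, z_max) {
  stopifnot(y_half_width > 0, z_min < z_max)
  structure(list(y_half_width = y_half_width, z_min = z_min, z_max = z_max),
            class = "region_spec")
}

#' Default modulated regions for the study beams
#'
#' Depth limits 2.0, 4.5 and 6.5 cm for the 7, 13 and 20 MeV beams
#' (slightly beyond each beam's R90), 0.5 cm minimum depth, +/- 3.5 cm
#' laterally.
#'
#' @param label beam label, or NULL for the full list.
#' @return a `region_spec` or named list of them.
#' @export
default_regions <- function(label = NULL) {
  regions <- list(
    "7MeV"  = region_spec(z_max = 2.0),
    "13MeV" = region_spec(z_max = 4.5),
    "20MeV" = region_spec(z_max = 6.5)
  )
  if (is.null(label)) return(regions)
  if (!label %in% names(regions)) stop("unknown region label: ", label)
  regions[[label]]
}

# Logical index masks of a dose grid restricted to a region.
region_index <- function(grid, region) {
  iy <- which(abs(grid$y) <= region$y_half_width + 1e-9)
  iz <- which(grid$z >= region$z_min - 1e-9 & grid$z <= region$z_max + 1e-9)
  if (length(iy) == 0 || length(iz) == 0) stop("region contains no grid points")
  list(iy = iy, iz = iz)
}

check_same_grid <- function(a, b) {
  if (length(a$y) != length(b$y) || length(a$z) != length(b$z) ||
      max(abs(a$y - b$y)) > 1e-9 || max(abs(a$z - b$z)) > 1e-9) {
    stop("dose grids are not on the same coordinates; resample first")
  }
}

#' RMS dose difference over a region
#'
#' Root-mean-square of pointwise calculated-minus-measured dose
#' differences over the region, in percent of given dose.
#'
#' @param calc,meas [dose_grid()]s on identical coordinates.
#' @param region a [region_spec()].
#' @return RMS, percent.
#' @export
rms_percent <- function(calc, meas, region) {
  stopifnot(inherits(calc, "dose_grid"), inherits(meas, "dose_grid"),
            inherits(region, "region_spec"))
  check_same_grid(calc, meas)
  ri <- region_index(calc, region)
  d <- calc$values[ri$iy, ri$iz] - meas$values[ri$iy, ri$iz]
  sqrt(mean(d^2))
}

#' 2%/2mm agreement between calculated and measured dose grids
#'
#' Each measured point in the region passes if the calculated dose at the
#' same point agrees within `dose_tol` (percent of given dose, global
#' normalisation), or if the calculated distribution attains the measured
#' value within `dta_tol` of the point (distance to agreement).  The DTA
#' search walks grid segments in a window of half-size `dta_tol` around
#' the point, locating value crossings by linear interpolation along y-
#' and z-direction segments and checking their Euclidean distance.  The
#' measured grid is the reference (its points are evaluated).
#'
#' @param calc,meas [dose_grid()]s on identical coordinates (spacing must
#'   be at most `dta_tol / 2`).
#' @param region a [region_spec()].
#' @param dose_tol dose tolerance, percent of given dose.
#' @param dta_tol distance-to-agreement tolerance, cm.
#' @return object of class `agreement_report`: list with `rms_percent`,
#'   `pass_rate` (percent of evaluated points), `n_points`, and
#'   `fail_mask` (logical matrix over the region, TRUE = failing point).
#' @export
pass_rate_2pct_2mm <- function(calc, meas, region, dose_tol = 2,
                               dta_tol = 0.2) {
  stopifnot(inherits(region, "region_spec"), dose_tol > 0, dta_tol > 0)
  check_same_grid(calc, meas)
  hy <- if (length(calc$y) > 1) abs(diff(calc$y[1:2])) else Inf
  hz <- if (length(calc$z) > 1) abs(diff(calc$z[1:2])) else Inf
  if (min(hy, hz) > dta_tol / 2 + 1e-9) {
    stop("grid spacing too coarse for the DTA search (need <= dta_tol / 2)")
  }
  ri <- region_index(calc, region)
  C <- calc$values; M <- meas$values
  diff_ok <- abs(C[ri$iy, ri$iz, drop = FALSE] -
                 M[ri$iy, ri$iz, drop = FALSE]) <= dose_tol
  pass <- diff_ok
  ny <- length(calc$y); nz <- length(calc$z)
  wy <- ceiling(dta_tol / hy); wz <- ceiling(dta_tol / hz)
  for (a in seq_along(ri$iy)) {
    for (b in seq_along(ri$iz)) {
      if (pass[a, b]) next
      i <- ri$iy[a]; j <- ri$iz[b]
      dm <- M[i, j]
      y0 <- calc$y[i]; z0 <- calc$z[j]
      ilo <- max(1, i - wy); ihi <- min(ny, i + wy)
      jlo <- max(1, j - wz); jhi <- min(nz, j + wz)
      found <- FALSE
      for (jj in jlo:jhi) {
        dz <- calc$z[jj] - z0
        if (abs(dz) > dta_tol) next
        col <- C[ilo:ihi, jj]
        # crossings along y segments (frac = 0 handles node-exact matches)
        dv <- col - dm
        for (k in seq_len(length(col) - 1)) {
          if (dv[k] * dv[k + 1] <= 0) {
            frac <- if (dv[k] == dv[k + 1]) 0 else dv[k] / (dv[k] - dv[k + 1])
            yc <- calc$y[ilo + k - 1] + frac * hy
            if (sqrt((yc - y0)^2 + dz^2) <= dta_tol) { found <- TRUE; break }
          }
        }
        if (found) break
      }
      if (!found) {
        for (ii in ilo:ihi) {
          dy <- calc$y[ii] - y0
          if (abs(dy) > dta_tol) next
          row <- C[ii, jlo:jhi]
          dv <- row - dm
          for (k in seq_len(length(row) - 1)) {
            if (dv[k] * dv[k + 1] <= 0) {
              frac <- if (dv[k] == dv[k + 1]) 0 else dv[k] / (dv[k] - dv[k + 1])
              zc <- calc$z[jlo + k - 1] + frac * hz
              if (sqrt(dy^2 + (zc - z0)^2) <= dta_tol) { found <- TRUE; break }
            }
          }
          if (found) break
        }
      }
      pass[a, b] <- found
    }
  }
  n <- length(pass)
  structure(list(
    rms_percent = rms_percent(calc, meas, region),
    pass_rate = 100 * sum(pass) / n,
    n_points = n,
    fail_mask = !pass,
    region = region, dose_tol = dose_tol, dta_tol = dta_tol
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement over %d points: pass rate %.1f%% (%g%%/%g mm), RMS %.3f%%\n",
              x$n_points, x$pass_rate, x$dose_tol, 10 * x$dta_tol,
              x$rms_percent))
  invisible(x)
}

#' Calibrate the modified diameter against a measured dose grid
#'
#' Finds the single effective block diameter (shared by all blocks, at
#' the insert plane) minimising the sum of squared differences between
#' the measured grid and the forward model over the modulated region.  A
#' coarse pre-scan at 0.005 cm steps guards against non-unimodality; the
#' bracketing interval around the best scan point is then refined by
#' golden-section search ([stats::optimize()]) to 1e-4 cm.
#'
#' @param meas measured [dose_grid()] (its region sub-grid is the
#'   optimization target).
#' @param device a [prime_device()].
#' @param beam a [beam_spec()].
#' @param region a [region_spec()].
#' @param bounds length-2 diameter search interval, cm, inside (0, r).
#' @param ... forwarded to [calc_dose_grid()] (pdd, sigma_device, ...).
#' @return optimal diameter, cm, with attributes `objective` (residual
#'   sum of squares) and `rms_percent`.
#' @export
optimize_dmod <- function(meas, device, beam, region,
                          bounds = c(0.05, 0.95 * device$r), ...) {
  stopifnot(inherits(meas, "dose_grid"), inherits(region, "region_spec"))
  if (length(bounds) != 2 || bounds[1] >= bounds[2] ||
      bounds[1] <= 0 || bounds[2] >= device$r) {
    stop("bounds must be an increasing interval inside (0, r)")
  }
  ri <- region_index(meas, region)
  yv <- meas$y[ri$iy]; zv <- meas$z[ri$iz]
  target <- meas$values[ri$iy, ri$iz]
  obj <- function(d) {
    calc <- calc_dose_grid(device, beam, yv, zv, d_override = d, ...)
    v <- sum((calc$values - target)^2)
    if (!is.finite(v)) stop("non-finite calibration objective at d = ", d)
    v
  }
  grid <- seq(bounds[1], bounds[2], by = 0.005)
  if (grid[length(grid)] < bounds[2]) grid <- c(grid, bounds[2])
  vals <- vapply(grid, obj, numeric(1))
  k <- which.min(vals)
  lo <- grid[max(1, k - 1)]; hi <- grid[min(length(grid), k + 1)]
  opt <- stats::optimize(obj, c(lo, hi), tol = 1e-4)
  d_hat <- opt$minimum
  structure(d_hat, objective = opt$objective,
            rms_percent = sqrt(opt$objective / length(target)))
}
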