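#' Nominal intensity reduction factor of a hexagonal island-block lattice
#'
#' For island blocks of diameter `d_nom` on a hexagonal grid with packing
#' radius `r`, the unblocked area fraction of the unit cell is
#' \deqn{IRF_{nom} = 1 - \frac{\pi}{2\sqrt{3}} \left(\frac{d_{nom}}{r}\right)^2.}
#' This is the fraction of local planar fluence transmitted when the
#' blocks act as perfect collimators.
#'
#' @param d_nom block diameter, cm (vectorised).
#' @param r hexagonal packing radius (nearest-neighbour spacing), cm.
#' @return dimensionless transmission fraction in (0, 1].
#' @examples
#' irf_nominal(0.158, 0.6)  # 0.937
#' irf_nominal(0.352, 0.6)  # 0.688
#' @export
irf_nominal <- function(d_nom, r) {
  stopifnot(is.numeric(d_nom), is.numeric(r))
  if (any(d_nom < 0)) stop("d_nom must be nonnegative")
  if (any(r <= 0)) stop("r must be positive")
  if (any(d_nom >= r)) stop("d_nom must be < r (blocks would overlap)")
  1 - pi / (2 * sqrt(3)) * (d_nom / r)^2
}

#' Construct a PRIME device from an explicit block list
#'
#' A PRIME device is a set of cylindrical tungsten island blocks embedded
#' in a machinable foam slab inside the collimating insert.  Positions and
#' diameters are canonical at the insert plane (`source_to_isocenter -
#' insert_to_isocenter` cm from the source).
#'
#' @param blocks data.frame with columns `x` (cross-plane, cm), `y`
#'   (in-plane, cm), `d` (diameter, cm) and optionally `length`
#'   (cm, default 0.6), all at the insert plane.
#' @param r hexagonal packing radius, cm.
#' @param foam_thickness,foam_density foam slab thickness (cm) and
#'   density (g cm^-3).
#' @param insert_to_isocenter,source_to_isocenter geometry, cm.
#' @param field_extent optional c(extent_x, extent_y) declared field size
#'   at the insert plane; blocks must lie within it.
#' @return object of class `prime_device`.
#' @seealso [build_hex_device()], [read_device_file()]
#' @export
prime_device <- function(blocks, r = 0.6, foam_thickness = 1.27,
                         foam_density = 0.096, insert_to_isocenter = 5,
                         source_to_isocenter = 100, field_extent = NULL) {
  if (is.null(blocks) || nrow(blocks) == 0) {
    blocks <- data.frame(x = numeric(0), y = numeric(0), d = numeric(0),
                         length = numeric(0))
  }
  stopifnot(is.data.frame(blocks), all(c("x", "y", "d") %in% names(blocks)))
  if (is.null(blocks$length)) blocks$length <- rep(0.6, nrow(blocks))
  if (r <= 0) stop("packing radius r must be positive")
  if (foam_thickness <= 0) stop("foam_thickness must be positive")
  if (nrow(blocks) > 0) {
    if (any(blocks$d <= 0)) stop("block diameters must be positive")
    if (any(blocks$length <= 0)) stop("block lengths must be positive")
    if (any(blocks$d >= r)) stop("block diameter >= packing radius: blocks overlap")
    if (nrow(blocks) > 1) {
      dmin <- min(stats::dist(blocks[, c("x", "y")]))
      if (dmin < r - 1e-9) {
        stop(sprintf("minimum block spacing %.6g cm is below packing radius %g cm",
                     dmin, r))
      }
    }
    if (!is.null(field_extent)) {
      if (any(abs(blocks$x) > field_extent[1] / 2 + 1e-9) ||
          any(abs(blocks$y) > field_extent[2] / 2 + 1e-9)) {
        stop("blocks outside the declared field extent")
      }
    }
  }
  structure(list(
    blocks = blocks[, c("x", "y", "d", "length")],
    r = r,
    foam_thickness = foam_thickness,
    foam_density = foam_density,
    insert_to_isocenter = insert_to_isocenter,
    source_to_isocenter = source_to_isocenter,
    field_extent = field_extent
  ), class = "prime_device")
}

#' @export
print.prime_device <- function(x, ...) {
  n <- nrow(x$blocks)
  cat("PRIME device:", n, "island block(s) on a", x$r,
      "cm hexagonal grid (insert plane)\n")
  if (n > 0) {
    cat(sprintf("  diameters: %s cm; IRF_nom (uniform d): %s\n",
                paste(signif(sort(unique(x$blocks$d)), 4), collapse = ", "),
                if (length(unique(x$blocks$d)) == 1)
                  signif(irf_nominal(x$blocks$d[1], x$r), 4) else "mixed"))
  }
  cat(sprintf("  foam: %g cm, %g g/cm^3; insert at %g cm from source\n",
              x$foam_thickness, x$foam_density,
              x$source_to_isocenter - x$insert_to_isocenter))
  invisible(x)
}

#' Build a centered hexagonal island-block lattice
#'
#' Generates a hexagonal lattice centered on the origin with a block at
#' (0, 0): rows at `y = k * (sqrt(3)/2) * r` for integer `k`, even rows at
#' `x = m * r`, odd rows offset by `r/2`.  Sites are kept when
#' `|x| <= extent_x/2` and `|y| <= extent_y/2`, boundaries inclusive to
#' within 1e-9 cm, so an 8.4 cm extent at r = 0.6 cm includes the sites at
#' exactly +/-4.2 cm and yields the standard 247-block test device.
#'
#' @param extent_x,extent_y field extent at the insert plane, cm.
#' @param r hexagonal packing radius, cm.
#' @param d_nom common block diameter, cm.
#' @param ... passed to [prime_device()] (foam and geometry metadata).
#' @return a `prime_device`.
#' @examples
#' dev <- build_hex_device(8.4, 8.4, 0.6, 0.273)
#' nrow(dev$blocks)  # 247
#' @export
build_hex_device <- function(extent_x, extent_y, r, d_nom, ...) {
  stopifnot(extent_x > 0, extent_y > 0, r > 0, d_nom > 0)
  tol <- 1e-9
  dy <- sqrt(3) / 2 * r
  kmax <- floor((extent_y / 2 + tol) / dy)
  rows <- lapply(seq(-kmax, kmax), function(k) {
    off <- if (k %% 2 == 0) 0 else 0.5
    # |(m + off) * r| <= extent_x/2
    mmax <- floor((extent_x / 2 + tol) / r - off)
    mmin <- -floor((extent_x / 2 + tol) / r + off)
    m <- seq(mmin, mmax)
    data.frame(x = (m + off) * r, y = k * dy)
  })
  blocks <- do.call(rbind, rows)
  blocks$d <- d_nom
  prime_device(blocks, r = r, field_extent = c(extent_x, extent_y), ...)
}

#' Divergent-beam projection between planes
#'
#' Scales a lateral position or diameter between two planes perpendicular
#' to the beam axis, assuming rays diverge from the nominal source:
#' `value * to_distance / from_distance`, distances measured from the
#' source.  Device files store isocenter-projected values (100 cm); the
#' canonical internal plane is the insert plane (95 cm by default).
#'
#' @param value length to scale, cm (vectorised).
#' @param from_distance,to_distance source distances of the two planes, cm.
#' @return scaled length, cm.
#' @export
project_between_planes <- function(value, from_distance, to_distance) {
  if (any(from_distance <= 0) || any(to_distance <= 0)) {
    stop("plane distances from source must be positive")
  }
  value * (to_distance / from_distance)
}
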