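#' Write a PRIME device file
#'
#' Device file dialect: UTF-8 text; `#`-comment header lines carrying
#' `key: value` metadata (packing radius, foam thickness/density,
#' geometry, plane); first non-comment line the integer block count N;
#' then N whitespace-separated rows `x_iso y_iso d_iso` in cm, positions
#' and diameters projected to isocenter by divergent-beam scaling.
#'
#' @param device a [prime_device()] (insert-plane canonical coordinates).
#' @param path output file.
#' @export
write_device_file <- function(device, path) {
  stopifnot(inherits(device, "prime_device"))
  sad <- device$source_to_isocenter
  plane_from <- sad - device$insert_to_isocenter
  proj <- function(v) project_between_planes(v, plane_from, sad)
  fmt <- function(v) formatC(v, digits = 12, format = "g")
  hdr <- c(
    "# PRIME device file (positions/diameters in cm, projected to isocenter)",
    paste0("# plane: isocenter"),
    paste0("# packing_radius_insert_cm: ", fmt(device$r)),
    paste0("# foam_thickness_cm: ", fmt(device$foam_thickness)),
    paste0("# foam_density_g_cm3: ", fmt(device$foam_density)),
    paste0("# insert_to_isocenter_cm: ", fmt(device$insert_to_isocenter)),
    paste0("# source_to_isocenter_cm: ", fmt(sad))
  )
  if (!is.null(device$field_extent)) {
    hdr <- c(hdr, paste0("# field_extent_insert_cm: ",
                         paste(fmt(device$field_extent), collapse = " ")))
  }
  n <- nrow(device$blocks)
  rows <- if (n > 0) {
    paste(fmt(proj(device$blocks$x)), fmt(proj(device$blocks$y)),
          fmt(proj(device$blocks$d)))
  } else character(0)
  writeLines(c(hdr, as.character(n), rows), path)
  invisible(path)
}

#' Read a PRIME device file
#'
#' Parses the dialect of [write_device_file()] and converts the
#' isocenter-projected positions and diameters back to the canonical
#' insert plane.  Malformed rows, negative diameters, or a count
#' mismatch raise an error naming the offending line.
#'
#' @param path device file.
#' @return a [prime_device()].
#' @export
read_device_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta <- list()
  for (ln in grep("^#", lines, value = TRUE)) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z0-9_]+):\\s*(.+?)\\s*$", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  body_idx <- which(!grepl("^\\s*(#|$)", lines))
  if (length(body_idx) == 0) stop("device file has no block-count line")
  n <- suppressWarnings(as.integer(trimws(lines[body_idx[1]])))
  if (is.na(n) || n < 0) {
    stop("line ", body_idx[1], ": block count must be a nonnegative integer")
  }
  row_idx <- body_idx[-1]
  if (length(row_idx) != n) {
    stop("block count ", n, " does not match ", length(row_idx), " data rows")
  }
  num <- function(key, default) {
    if (is.null(meta[[key]])) default else as.numeric(meta[[key]])
  }
  sad <- num("source_to_isocenter_cm", 100)
  ins <- num("insert_to_isocenter_cm", 5)
  plane_from <- sad - ins
  blocks <- NULL
  if (n > 0) {
    parsed <- lapply(row_idx, function(i) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
      if (length(v) != 3 || any(is.na(v))) {
        stop("line ", i, ": expected three numeric fields 'x_iso y_iso d_iso'")
      }
      if (v[3] <= 0) stop("line ", i, ": nonpositive diameter")
      v
    })
    m <- do.call(rbind, parsed)
    blocks <- data.frame(
      x = project_between_planes(m[, 1], sad, plane_from),
      y = project_between_planes(m[, 2], sad, plane_from),
      d = project_between_planes(m[, 3], sad, plane_from)
    )
  }
  extent <- if (!is.null(meta$field_extent_insert_cm)) {
    as.numeric(strsplit(meta$field_extent_insert_cm, "\\s+")[[1]])
  } else NULL
  prime_device(blocks,
               r = num("packing_radius_insert_cm", 0.6),
               foam_thickness = num("foam_thickness_cm", 1.27),
               foam_density = num("foam_density_g_cm3", 0.096),
               insert_to_isocenter = ins, source_to_isocenter = sad,
               field_extent = extent)
}

#' Default run configuration
#'
#' Bundles the study beams, calibrated per-energy lateral spreads, the
#' default modified-diameter coefficients, per-energy evaluation regions,
#' and the foam adjustment flags (50% increase of the incident angular
#' spread on by default; the R90 shift and energy reduction off, matching
#' commissioning with the foam in place).
#'
#' @return named list (class `run_config`).
#' @export
default_run_config <- function() {
  structure(list(
    beams = study_beams(),
    sigma_x_cm = as.list(calibrated_sigma_x_table()),
    dmod_coefficients = dmod_coefficients(),
    regions = default_regions(),
    flags = list(foam_sigma_theta_factor = 1.5,
                 r90_shift_cm = 0,
                 e_p0_shift_mev = 0)
  ), class = "run_config")
}

#' Read a YAML run configuration
#'
#' Reads a YAML file and merges it over [default_run_config()].
#' Recognised top-level keys: `beams` (label -> e_p0/ssd/r100/r90/rp/
#' x_ray_background), `sigma_x_cm` (label -> cm), `dmod_coefficients`
#' (a0..a5), `regions` (label -> y_half_width/z_min/z_max), `flags`.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- default_run_config()
  y <- yaml::read_yaml(path)
  if (!is.null(y$beams)) {
    for (lab in names(y$beams)) {
      cfg$beams[[lab]] <- do.call(beam_spec, y$beams[[lab]])
    }
  }
  if (!is.null(y$sigma_x_cm)) {
    cfg$sigma_x_cm <- utils::modifyList(cfg$sigma_x_cm, y$sigma_x_cm)
  }
  if (!is.null(y$dmod_coefficients)) {
    cfg$dmod_coefficients <- do.call(dmod_coefficients, y$dmod_coefficients)
  }
  if (!is.null(y$regions)) {
    for (lab in names(y$regions)) {
      cfg$regions[[lab]] <- do.call(region_spec, y$regions[[lab]])
    }
  }
  if (!is.null(y$flags)) cfg$flags <- utils::modifyList(cfg$flags, y$flags)
  cfg
}
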