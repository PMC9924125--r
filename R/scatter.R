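#' Side of the square with the block's cross-sectional area
#'
#' Pencil-beam in-scatter theory replaces each cylindrical block by a
#' right square parallelepiped of equal cross-sectional area, so
#' `s = d_nom * sqrt(pi) / 2` (then `s^2 = pi d^2 / 4`).
#'
#' @param d_nom block diameter, cm (vectorised, nonnegative).
#' @return square side, cm.
#' @export
equivalent_square_side <- function(d_nom) {
  if (any(d_nom < 0)) stop("d_nom must be nonnegative")
  d_nom * sqrt(pi) / 2
}

#' Parameters of the multiple-Coulomb-scattering lateral spread model
#'
#' @param sigma_theta_x projected angular spread of the incident beam,
#'   radians (optionally already increased by the 50% foam factor).
#' @param mass_scattering_power mass angular scattering power of the foam
#'   at the beam energy, radian^2 cm^2 g^-1.
#' @param foam_density g cm^-3.
#' @param foam_thickness cm.
#' @return object of class `scatter_params`.
#' @export
scatter_params <- function(sigma_theta_x, mass_scattering_power,
                           foam_density = 0.096, foam_thickness = 1.27) {
  stopifnot(sigma_theta_x >= 0, mass_scattering_power >= 0,
            foam_density >= 0, foam_thickness > 0)
  structure(list(sigma_theta_x = sigma_theta_x,
                 mass_scattering_power = mass_scattering_power,
                 foam_density = foam_density,
                 foam_thickness = foam_thickness),
            class = "scatter_params")
}

#' RMS lateral spread of a pencil beam after the foam slab
#'
#' \deqn{\sigma_x = t\,[\sigma_{\theta x}^2 +
#'   \tfrac{1}{6} (T/\rho)_{foam}\, \rho_{foam}\, t]^{1/2}}
#' where the first term is drift of the incident angular spread over the
#' slab thickness and the second the Fermi-Eyges growth from scattering
#' inside the slab.
#'
#' @param params a [scatter_params()] object.
#' @return sigma_x, cm.
#' @export
sigma_x_foam <- function(params) {
  stopifnot(inherits(params, "scatter_params"))
  t <- params$foam_thickness
  t * sqrt(params$sigma_theta_x^2 +
             params$mass_scattering_power * params$foam_density * t / 6)
}

# 1-D probability that a uniform launch point on a slit of width s,
# blurred by a zero-mean Gaussian of RMS sigma_x, stays inside the slit;
# w = s / (sqrt(2) sigma_x).  Series fallback near w = 0 avoids 0/0.
slit_containment <- function(w) {
  p <- ifelse(w < 1e-6,
              (w - w^3 / 6) / sqrt(pi),
              erf(w) + (exp(-w^2) - 1) / (w * sqrt(pi)))
  pmin(pmax(p, 0), 1)
}

#' In-scatter fraction of an island block
#'
#' Ratio of the number of electrons scattered into the sides of an island
#' block to the number incident on its upstream face, from pencil-beam
#' theory for the equivalent square block of side `s`.  With
#' `w = s / (sqrt(2) sigma_x)` and the 1-D slit containment probability
#' \deqn{P(w) = \mathrm{erf}(w) + \frac{1}{w\sqrt{\pi}}(e^{-w^2} - 1),}
#' the two-dimensional containment is `P(w)^2` and
#' \deqn{f = 1 - P(w)^2.}
#' `f` is strictly increasing in `sigma_x` and decreasing in `s`;
#' `sigma_x = 0` gives exactly 0 (no lateral spread, no side scatter) and
#' `sigma_x -> Inf` gives 1.
#'
#' @param s equivalent square side, cm ([equivalent_square_side()]).
#' @param sigma_x RMS lateral spread of the pencil beam, cm (vectorised).
#' @return dimensionless fraction in \[0, 1).
#' @export
inscatter_fraction <- function(s, sigma_x) {
  if (any(s <= 0)) stop("s must be positive")
  if (any(sigma_x < 0)) stop("sigma_x must be nonnegative")
  n <- max(length(s), length(sigma_x))
  s <- rep_len(s, n); sigma_x <- rep_len(sigma_x, n)
  w <- ifelse(sigma_x == 0, Inf, s / (sqrt(2) * sigma_x))
  ifelse(is.infinite(w), 0, 1 - slit_containment(w)^2)
}

#' Calibrate the lateral spread from a known in-scatter fraction
#'
#' Inverts [inscatter_fraction()] for `sigma_x` by bisection, exploiting
#' strict monotonicity of f in sigma_x.  Used to fix one sigma_x per beam
#' energy from a single tabulated f value (the published in-scatter tables
#' quote f but not the underlying angular spread).
#'
#' @param s equivalent square side, cm.
#' @param f_target in-scatter fraction in (0, 1).
#' @return sigma_x, cm, such that `inscatter_fraction(s, sigma_x)` equals
#'   `f_target` to within 1e-10.
#' @export
calibrate_sigma_x <- function(s, f_target) {
  stopifnot(length(f_target) == 1, length(s) == 1)
  if (!(f_target > 0 && f_target < 1)) stop("f_target must be in (0, 1)")
  lo <- 1e-6; hi <- 10 * s
  flo <- inscatter_fraction(s, lo); fhi <- inscatter_fraction(s, hi)
  while (fhi < f_target) { hi <- 2 * hi; fhi <- inscatter_fraction(s, hi) }
  if (flo > f_target) return(lo)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (inscatter_fraction(s, mid) < f_target) lo <- mid else hi <- mid
    if (hi - lo < 1e-12) break
  }
  (lo + hi) / 2
}

#' In-scatter-adjusted effective diameter
#'
#' In-scattered electrons remove additional fluence equivalent to
#' enlarging the block: `d_IS = d_nom * sqrt(1 + f)`.
#'
#' @param d_nom nominal diameter, cm (vectorised).
#' @param f in-scatter fraction in \[0, 1).
#' @return effective diameter, cm.
#' @export
d_in_scatter <- function(d_nom, f) {
  if (any(d_nom < 0)) stop("d_nom must be nonnegative")
  if (any(f < 0 | f >= 1)) stop("f must be in [0, 1)")
  d_nom * sqrt(1 + f)
}

#' In-scatter-adjusted intensity reduction factor
#'
#' `IRF_IS = IRF_nom - f * (1 - IRF_nom)`: the blocked fraction
#' `(1 - IRF_nom)` grows by the side-scattered fraction f.  Algebraically
#' identical to applying [irf_nominal()] to [d_in_scatter()].
#'
#' @param irf_nom nominal IRF in (0, 1\] (vectorised).
#' @param f in-scatter fraction in \[0, 1).
#' @return adjusted IRF.
#' @export
irf_in_scatter <- function(irf_nom, f) {
  if (any(irf_nom <= 0 | irf_nom > 1)) stop("irf_nom must be in (0, 1]")
  if (any(f < 0 | f >= 1)) stop("f must be in [0, 1)")
  irf_nom - f * (1 - irf_nom)
}

#' In-scatter adjustment of a block at one energy
#'
#' Convenience wrapper bundling [inscatter_fraction()], [d_in_scatter()]
#' and [irf_in_scatter()] for a block of diameter `d_nom` on a grid of
#' packing radius `r`.
#'
#' @param d_nom nominal diameter, cm.
#' @param r packing radius, cm.
#' @param sigma_x RMS lateral spread, cm.
#' @return list with elements `f`, `d_is`, `irf_is`.
#' @export
inscatter_adjust <- function(d_nom, r, sigma_x) {
  f <- inscatter_fraction(equivalent_square_side(d_nom), sigma_x)
  list(f = f, d_is = d_in_scatter(d_nom, f),
       irf_is = irf_in_scatter(irf_nominal(d_nom, r), f))
}

#' Coefficients of the modified-diameter quadratic surface
#'
#' The empirically calibrated effective diameter is parameterised as a
#' quadratic in nominal diameter d (cm) and most probable beam energy E
#' (MeV):
#' \deqn{d_{mod} = A_0 + A_1 d + A_2 E + A_3 d^2 + A_4 d E + A_5 E^2.}
#' Defaults are the published fitted coefficients for the standard
#' 0.6 cm-pitch tungsten/foam modulators (units: cm, -, cm/MeV, 1/cm,
#' 1/MeV, cm/MeV^2).
#'
#' @param a0,a1,a2,a3,a4,a5 surface coefficients.
#' @return object of class `dmod_coefficients` (named numeric vector).
#' @export
dmod_coefficients <- function(a0 = 1.61e-2, a1 = 1.09, a2 = -2.51e-3,
                              a3 = -1.45e-1, a4 = -1.40e-3, a5 = 6.42e-5) {
  v <- c(a0 = a0, a1 = a1, a2 = a2, a3 = a3, a4 = a4, a5 = a5)
  if (any(!is.finite(v))) stop("coefficients must be finite")
  structure(v, class = "dmod_coefficients")
}

#' @export
print.dmod_coefficients <- function(x, ...) {
  cat("Modified-diameter surface d_mod(d, E) = a0 + a1 d + a2 E + a3 d^2 + a4 dE + a5 E^2\n")
  print(unclass(signif(x, 6)))
  invisible(x)
}

#' Modified (empirically calibrated) island block diameter
#'
#' Evaluates the quadratic surface of [dmod_coefficients()], which absorbs
#' both in-scatter (dominant at low energy, d_mod > d_nom) and out-scatter
#' (dominant at high energy, d_mod < d_nom).  The surface was calibrated
#' on diameters 0.158-0.352 cm and energies ~7-20.5 MeV; evaluation
#' outside that hull extrapolates and emits a warning.
#'
#' @param d_nom nominal diameter, cm (vectorised).
#' @param e_p0 most probable incident beam energy, MeV.
#' @param coeffs a [dmod_coefficients()] object.
#' @return modified diameter, cm.
#' @examples
#' d_modified(0.158, 20.47)  # ~0.156
#' @export
d_modified <- function(d_nom, e_p0, coeffs = dmod_coefficients()) {
  if (any(d_nom <= 0)) stop("d_nom must be positive")
  if (any(e_p0 < 7 | e_p0 > 20.5)) {
    warning("e_p0 outside the calibrated 7-20.5 MeV range; extrapolating")
  }
  unname(coeffs["a0"] + coeffs["a1"] * d_nom + coeffs["a2"] * e_p0 +
           coeffs["a3"] * d_nom^2 + coeffs["a4"] * d_nom * e_p0 +
           coeffs["a5"] * e_p0^2)
}

#' Least-squares fit of the modified-diameter surface
#'
#' Ordinary least squares of calibrated `d_mod` values on the 6-term
#' quadratic basis in (d_nom, e_p0).  Needs at least 6 points spanning at
#' least two distinct diameters and two distinct energies.
#'
#' @param points data.frame with columns `d_nom` (cm), `e_p0` (MeV),
#'   `d_mod` (cm).
#' @return fitted [dmod_coefficients()].
#' @export
fit_dmod_surface <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("d_nom", "e_p0", "d_mod") %in% names(points)))
  if (nrow(points) < 6) stop("need at least 6 calibration points")
  if (length(unique(points$d_nom)) < 2 || length(unique(points$e_p0)) < 2) {
    stop("calibration points must span >= 2 diameters and >= 2 energies")
  }
  X <- with(points, cbind(1, d_nom, e_p0, d_nom^2, d_nom * e_p0, e_p0^2))
  if (qr(X)$rank < 6) stop("rank-deficient quadratic basis")
  beta <- unname(qr.solve(X, points$d_mod))
  dmod_coefficients(beta[1], beta[2], beta[3], beta[4], beta[5], beta[6])
}
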