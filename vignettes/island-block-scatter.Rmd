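---
title: "Modeling island-block scatter in passive electron intensity modulators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling island-block scatter in passive electron intensity modulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primescatter)
```

## The problem

Intensity-modulated bolus electron conformal therapy (IM-BECT) shapes an
electron beam's dose distribution with a variable-thickness bolus and a
passive intensity modulator: a lattice of short cylindrical tungsten rods
("island blocks") embedded in a low-density machinable foam slab inside
the patient-specific collimating insert.  Electrons hitting a block's
upstream face are absorbed; upstream scatter in air and foam restores
lateral fluence uniformity a few centimetres downstream, so the device
multiplies the local planar fluence by an intensity reduction factor
(IRF).  For blocks of diameter $d_{nom}$ on a hexagonal grid of packing
radius $r$, the unit cell's unblocked area fraction gives

$$\mathrm{IRF}_{nom} = 1 - \frac{\pi}{2\sqrt 3}\left(\frac{d_{nom}}{r}\right)^2 .$$

Treating the blocks as perfect collimators ignores two effects that this
package models:

* **In-scatter** — electrons that would have missed a block are scattered
  in air/foam into its side and absorbed, removing extra fluence.  This
  dominates at low beam energy (larger scattering power) and makes the
  block act *larger* than its physical diameter.
* **Out-scatter** — electrons entering a block escape through its side
  with degraded energy, restoring fluence.  This dominates at high energy
  (longer range in tungsten) and makes the block act *smaller*.

Both effects are absorbed into effective block diameters that slot
directly into any fluence model that subtracts per-block shadows, keeping
the cost of the correction negligible.

## In-scatter from pencil-beam theory

Each cylinder is replaced by a square parallelepiped of equal
cross-sectional area, side $s = d_{nom}\sqrt{\pi}/2$.  A pencil beam
launched uniformly over the square and blurred by a zero-mean Gaussian of
RMS lateral spread $\sigma_x$ stays inside a slit of width $s$ with
probability

$$P(w) = \operatorname{erf}(w) + \frac{1}{w\sqrt{\pi}}\left(e^{-w^2}-1\right),
  \qquad w = \frac{s}{\sqrt 2\,\sigma_x},$$

so the fraction of electrons scattered into the block's sides, relative
to those incident on its upstream face, is the complement of the 2-D
containment:

$$f = 1 - P(w)^2 .$$

`inscatter_fraction()` implements this form, with a series expansion of
$P$ for $w < 10^{-6}$ to avoid 0/0, and an exact zero at $\sigma_x = 0$.
It is validated two independent ways: a Monte-Carlo oracle (uniform
launch points plus Gaussian displacements, scoring
$1 - \hat p^2$) agrees within sampling error, and a *single* $\sigma_x$
per beam energy, calibrated to the published $f$ of the smallest
(0.158 cm) block, reproduces the published $f$ of the other two block
sizes at that energy to within $\pm 0.001$ — nine table entries from
three fitted numbers.

The in-scatter fraction converts to effective geometry by

$$d_{IS} = d_{nom}\sqrt{1+f}, \qquad
  \mathrm{IRF}_{IS} = \mathrm{IRF}_{nom} - f\,(1-\mathrm{IRF}_{nom}),$$

which are algebraically consistent: applying the IRF formula to $d_{IS}$
reproduces $\mathrm{IRF}_{IS}$ exactly.

When beam-line parameters are available, the spread after the foam slab
of thickness $t$ can instead be computed from first principles
(`sigma_x_foam()`):

$$\sigma_x = t\left[\sigma_{\theta x}^2 +
  \tfrac16\,(T/\rho)_{foam}\,\rho_{foam}\,t\right]^{1/2}.$$

The published commissioning tables quote $f$ but not
$\sigma_{\theta x}$ or $(T/\rho)_{foam}$, so the package's default route
is calibration by inversion (`calibrate_sigma_x()`, bisection on
$\sigma_x \in [10^{-6}, 10s]$, monotone in $\sigma_x$); the calibrated
values are about 0.042, 0.025 and 0.016 cm at 7, 13 and 20 MeV.  Whether
the quoted fractions included the 50% foam increase of
$\sigma_{\theta x}$ is immaterial to this route, since the calibration
absorbs it.

## The modified diameter surface

Out-scatter resists closed-form treatment (escaping electrons have broad
energy and angle spectra), so the combined effect is captured
empirically: for each (device, energy) pair a single effective diameter
$d_{mod}$ is found by least squares against a measured dose grid, and the
nine calibrated values are smoothed by a quadratic response surface

$$d_{mod}(d_{nom}, E_{p,0}) = A_0 + A_1 d_{nom} + A_2 E_{p,0}
  + A_3 d_{nom}^2 + A_4 d_{nom} E_{p,0} + A_5 E_{p,0}^2 ,$$

with the published coefficients as defaults (`dmod_coefficients()`).
`fit_dmod_surface()` refits the surface by ordinary least squares on the
6-term basis (QR solve; at least six points spanning two diameters and
two energies required).  With the default coefficients the surface
reproduces the nine calibrated diameters within 0.003 cm — the printed
3-significant-figure coefficients limit agreement — and refitting
reduces residuals below 0.0004 cm.  $d_{mod} > d_{nom}$ at 7 MeV,
$d_{mod} \approx d_{nom}$ at 13 MeV, and $d_{mod} < d_{nom}$ at 20 MeV.
Evaluation outside the studied hull (0.158–0.352 cm, 7–20.5 MeV)
extrapolates with a warning.

A note on rounding: published per-row IRF values for $d_{mod}$ are not
always consistent with applying the IRF formula to the *printed*
(3-decimal) $d_{mod}$; the package always computes IRFs from unrounded
diameters and documents rather than reconciles the discrepancy.

## Forward fluence and dose model

`device_fluence()` subtracts, from an open-field fluence of 1 (with an
erf penumbra of RMS `sigma_edge` when the field is finite), one
Gaussian-blurred square shadow per block:

$$\phi(x,y) = \phi_{open}(x,y) - \sum_i
  H\!\left(x-x_i;\tfrac{s_i}{2},\sigma\right)
  H\!\left(y-y_i;\tfrac{s_i}{2},\sigma\right),$$

where $H$ is the 1-D Gaussian-convolved top-hat (`blurred_step()`) and
$s_i$ the equivalent-square side of the mode-selected diameter (nominal,
in-scatter, or modified).  Because convolution conserves area, each
shadow removes exactly $s_i^2$ of integrated fluence at every blur, and
the mean transmission under a periodic lattice equals the IRF of the
chosen diameter independent of $\sigma$ — both are asserted by numeric
quadrature in the tests.

`calc_dose_grid()` builds a 2-D in-plane dose matrix the way scanned
water-phantom data are assembled: $D(y,z) = \mathrm{PDD}(z)\times
\mathrm{OAR}(y,z)$ on a 0.1 cm grid, with 100% the central-axis maximum
of the foam-only device.  Block positions and diameters, canonical at the
insert plane (95 cm from source), are projected to the phantom surface by
divergent-beam scaling.  The depth-dependent blur combines the device
contribution with growth in water:

$$\sigma(z)^2 = \sigma_{device}^2 + \sigma_w(z)^2, \qquad
  \sigma_w(z) = k\,z^{3/2}/\sqrt{E_{p,0}} .$$

This single-redefinition Gaussian transport is the package's own
simplified engine, not a pencil-beam redefinition algorithm: it performs
one redefinition at the phantom surface and ignores heterogeneity,
energy binning (a single effective bin, consistent with assuming the
scattered spectrum equals the incident one), and insert-edge scatter.
Defaults were fixed once on physical grounds: $k = 0.3$
cm$^{-1/2}$MeV$^{1/2}$ gives millimetre spreads at shallow depths rising
to ~1 cm near the practical range; $\sigma_{device}$ is derived from the
calibrated foam-exit spread drifting across half the foam plus the 5 cm
insert-to-isocenter air gap (≈0.19/0.11/0.07 cm at 7/13/20 MeV); the
open-field penumbra RMS defaults to 0.3 cm and is a free configuration
parameter, since no penumbra model is prescribed for the source data.

## Calibration and agreement metrics

`optimize_dmod()` minimises
$\sum_{i,j}\left[D_{meas}(y_i,z_j) - D_{calc}(d; y_i,z_j)\right]^2$
over a single shared block diameter, within the modulated region
(default $|y| \le 3.5$ cm, $0.5 \le z \le z_{max}$ with $z_{max}$ = 2.0,
4.5, 6.5 cm at 7, 13, 20 MeV — slightly beyond each beam's $R_{90}$).  A
coarse 0.005 cm pre-scan guards against non-unimodality before
golden-section refinement to $10^{-4}$ cm.  One diameter per (device,
energy) pair; per-block optimisation is out of scope.

`rms_percent()` and `pass_rate_2pct_2mm()` evaluate agreement.  Dose
differences are globally normalised (% of given dose).  A measured point
passes at 2%/2mm if the same-position dose difference is within
tolerance *or* the calculated distribution attains the measured value
within 2 mm.  The measured grid is the reference; the DTA search is
confined to the 2-D measurement plane, walking y- and z-direction grid
segments in a window of half-size `dta_tol` and locating value crossings
by linear interpolation (no sub-grid optimisation beyond interpolation
— the source analyses do not state whether they interpolated, so
interpolation is adopted and flagged here).

## Synthetic measured data

Real commissioning uses water-phantom scans; the package ships a
generator with the same structure so the whole calibration loop is
exercisable and testable offline.  `gen_pdd()` is an analytic
depth-dose stand-in through user-supplied landmarks: a cosine build-up
from 85% at the surface to exactly 100 at $R_{100}$, a shaped cosine
falloff whose exponent is solved so the curve passes exactly through 90
at $R_{90}$, reaching the x-ray background at $R_p$ and constant beyond.
It makes no claim about true clinical depth-dose shapes; landmarks for
the three study energies are rule-of-thumb values ($R_p \approx
E_{p,0}/2$; $R_{90}$ just below the evaluation depth limit).
`gen_measured_grid()` samples the forward model at a ground-truth
diameter and adds seeded homoscedastic Gaussian noise (% of given dose);
detector volume averaging and positioning error are not simulated.

Because the synthetic "measurement" shares the forward model's physics,
parameter-recovery tests demonstrate the *calibration machinery* —
identifiability, optimizer correctness, noise robustness (recovery
within 0.002 cm noiseless and 0.005 cm at 0.5% noise over 20 seeded
replicates) — not forward-model accuracy against real scans, which
requires water-tank data.  Test problem sizes (a 4.5 cm lateral
half-extent at 7 MeV for recovery loops; $4\times10^6$ Monte-Carlo
samples per in-scatter check) were chosen to make those statistical
bounds tight while keeping the suite quick to run.

## Numerical choices and degenerate inputs

* Lattice generation is centered with a block at (0,0); boundary sites
  are included within a $10^{-9}$ cm tolerance, so the standard
  8.4 × 8.4 cm², $r = 0.6$ cm device has exactly 247 blocks (the lattice
  phase is not otherwise pinned down by the source description; the
  centered convention reproduces the published count and is adopted as
  normative).
* Device files store isocenter-projected values; reading converts to the
  insert plane.  Values are written with 12 significant digits so a
  read–write cycle is byte-stable.
* $f$ at $\sigma_x = 0$ returns exactly 0; $s \le 0$ is a domain error;
  degenerate lattice extents collapse to the single center block.
* Block attenuation is not modeled (blocks are total absorbers); block
  axes are not tilted with beam divergence; copper-insert edge scatter
  and 3-D dose are out of scope.
* The foam adjustments used with measured input data are configuration
  flags: the 50% increase of $\sigma_{\theta x}$ defaults to on; the
  $-0.1$ cm $R_{90}$ shift and $-0.2$ MeV energy reduction default to
  off, matching commissioning with the foam present during PDD
  measurement.

## A complete loop

```{r loop, eval = FALSE}
device <- build_hex_device(8.4, 8.4, 0.6, 0.273)
beam <- study_beams("7MeV")

# synthetic "measurement" at a known effective diameter
cfg <- synthetic_config(beam, device, d_true = 0.283, noise_sd = 0.5, seed = 1)
meas <- gen_measured_grid(cfg)

# calibrate the modified diameter and evaluate agreement
d_hat <- optimize_dmod(meas, device, beam, default_regions("7MeV"),
                       bounds = c(0.2, 0.35))
calc <- calc_dose_grid(device, beam, meas$y, meas$z,
                       d_override = as.numeric(d_hat))
pass_rate_2pct_2mm(calc, meas, default_regions("7MeV"))
```

## Known limitations

The Gaussian single-redefinition transport underestimates the structure a
redefinition algorithm captures at depth; the modified diameter assumes
out-scattered electrons share the incident spectrum, which measured data
contradict at 20 MeV near the surface (differences up to several
percent on central axis, shrinking off-axis and with depth); and the
quadratic surface is only validated inside the studied diameter/energy
hull.  Applications needing IRFs well below ~0.7, non-0.6 cm spacing, or
greater SSDs should expect the effective-diameter approximation to
degrade.
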