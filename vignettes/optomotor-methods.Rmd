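---
title: "Methods: eye reconstruction, optomotor scoring and EMD time-constant estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eye reconstruction, optomotor scoring and EMD time-constant estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optomotor)
```

## The problem

Miniature insects sample the visual world with a few dozen ommatidia
spaced ~15–20° apart, yet still show a walking optomotor response:
surrounded by a rotating stripe drum they walk in circles that follow the
pattern. This package implements the quantitative chain that connects the
anatomy of such an eye to the tuning of that behavior: per-ommatidium
geometry from digitized landmarks, thin-lens optics, response scoring
from tracked walking paths, and a correlation-type elementary motion
detector (EMD) whose one free parameter — the temporal low-pass time
constant τ — is estimated from the behavioral tuning curve.

## Eye reconstruction

The landmark schema per ommatidium is: outer and inner lens tip, six
lens-base points, and one rhabdomere tip; three ocelli landmarks define
the head frame. The pipeline is:

1. **Head normalization.** The rigid transform mapping the ocelli
   centroid to the origin, the ocelli-plane normal to +z, and the first
   ocellus to +x within the plane. No scaling. Collinear ocelli are a
   hard error.
2. **Lens-base plane and circle.** The least-squares plane of the six
   base points (via SVD) realizes the orientation in which the projected
   base area is maximal; the points are projected into it and a circle is
   fitted by linear least squares (Kasa parameterization, exact for
   exact circles). The lens diameter is the fitted circle's diameter.
3. **Visual axis.** Two constructions are provided. `"top"` (default):
   the projection line from the fitted circle center through the outer
   lens tip. `"normal"`: the base-plane normal, oriented outward. For a
   rotationally symmetric lens the two coincide.
4. **Neighbor graph and interommatidial angles.** "Neighboring" is not
   anatomically defined, so the default is the Delaunay triangulation of
   the lens centers after an azimuthal-equidistant projection about their
   mean viewing direction (faithful for the cap-like layout of a compound
   eye); a symmetric k-nearest-neighbor graph is available for partial
   reconstructions. The interommatidial angle per edge is the arccosine
   of the clamped dot product of the two unit axes — two vectors always
   span a plane, so this equals any sensible "in-plane" construction.

All derived scalars are invariant under rigid motion of the input cloud,
and on noiseless synthetic eyes the round trip reproduces diameters, axes
and angles to better than 1e-9 relative error (tested).

### Noise sensitivity of the two axis constructions

The outer lens tip sits only ~1.6 μm above the lens base plane. With
0.1 μm isotropic landmark noise — a realistic digitization error at
~0.3 μm image resolution — the `"top"` projection line therefore tilts by
several degrees per ommatidium, which inflates the *mean* pairwise angle
by ~1° (the angle between noisy unit vectors is biased upward). The
`"normal"` construction averages six base landmarks through the plane fit
and keeps the inflation an order of magnitude smaller. Both are exact on
noiseless data. The default remains `"top"` (it is the more explicit
prescription for digitized data); recovery checks on noisy synthetic eyes
use `"normal"`, and users reconstructing from noisy landmarks should
prefer it when lenses are thin relative to the noise.

## Lens optics

For a spherical dome of rim diameter `D` and apex height `h`,
`r = (D²/4 + h²)/(2h)`; `h = 0` returns an infinite radius (flat surface,
zero curvature term) rather than an error. The thin-lens focal length is
`1/l = (n_L − n_A)/r_air − (n_L − n_C)/r_cone` with defaults
n_L = 1.45, n_A = 1, n_C = 1.35. By default the air term receives the
**outer** radius of curvature — air meets the outer corneal surface —
with a `radius_assignment = "literal"` switch for the convention that
feeds the air term the inner radius (labelled r₁ in some figure
conventions); the physical assignment yields focal lengths near 19–20 μm
for typical miniature-eye radii, the literal one near 30 μm. The
acceptance angle is the small-angle ratio `Δρ = d/l` (radians, reported
in degrees) with `d` the mean rhabdomere spacing to graph neighbors.

Eye-level summaries are computed per ommatidium and then averaged, and
the two derived ratios (l/D, Δρ/Δϕ) are reported both as ratios of means
and as means of per-ommatidium ratios: the two differ because the
formulas are nonlinear in (D, h), and published eye-level numbers are
typically ratios of means.

## Behavior scoring

Trajectories are (t, x, y) centroid tracks at 60 frames/s, 68 s per run,
in a 15 mm radius container at the center of a 95 mm radius pattern drum
(drum circumference π·0.19 m ≈ 0.597 m). Scoring decisions that the
assay description leaves open, with defaults:

- **Walk time** (for the "< 10 s total walk time" exclusion) is the
  cumulative time with speed above 0.5 mm/s, where speed is measured
  from positions smoothed over 0.5 s and differenced across the same
  span — raw frame-to-frame displacement at 60 Hz is dominated by
  tracking jitter and would count resting as walking.
- **Wall following** ("exactly followed the circumference for > 3 s")
  means radial distance within 0.5 mm of the container radius for a
  contiguous span longer than 3 s. Both exclusion rules are always
  evaluated, so the flags are order-independent.
- **Rotation periods.** During circling the y-position trace has one peak
  per full body rotation; the period Δt is the spacing of successive
  local maxima (moving-average smoothing 0.25 s, topographic prominence
  ≥ 1 mm). Maxima — not inflection points in the calculus sense — are
  used; strict inflection points would halve the period. The detector is
  cross-checked against a brute-force every-local-maximum oracle.
- **Response.** `R = 360°/mean(Δt)` in deg/s, signed negative when the
  animal circles against the pattern (direction from the unwrapped phase
  about the path centroid). Period aggregation uses the per-trajectory
  mean.
- **Normalization** divides by the largest response magnitude within an
  experiment group, preserving sign; the grouping key is the caller's
  (one animal's condition series by default).
- **Onset latency.** Heading is estimated from displacement over a 0.25 s
  stride on smoothed positions; circling onset is a sustained (≥ 0.5 s)
  turning rate above 45 deg/s, refined by a two-mean least-squares
  changepoint on a fine-stride rate series — the split of a symmetrically
  blurred step sits at the transition midpoint, making the estimate
  unbiased to within a few hundredths of a second on synthetic data.
- **Egocentric correction.** A stripe period subtending λ from the arena
  center subtends λ·R_drum/distance from the animal; at the 80/110 mm
  walking-range extremes a 15° grating appears as 17.8°/13.0°. The
  nominal condition remains the analysis default (the deviations are
  small); the apparent bounds are reported for inspection.
- **Drum calibration.** Pattern speed from a tracked marker:
  `speed = n·360°/(frames/120 Hz)` over n = 10 full rotations, quantized
  to one calibration frame.

## EMD model and time-constant fit

The steady-state grating response is, with `x = 2πτυ/λ`,

`R = (1 + x²)^(-1/2) · sin(arctan x) · sin(2πΔϕ/λ) · (1 + (Δρ/λ)²)^(-1/2)`.

Angles enter in degrees with the 2π factors exactly as written (this is
what makes λ_max = 4Δϕ); `sin(arctan x)` is computed as `x/√(1+x²)`
(identical, stable for large |x|); the optics term is the printed
algebraic form, not a Gaussian modulation transfer function. The response
is odd in υ, bounded by 1, has aliasing zeros at λ = 2Δϕ/k, and its
normalized temporal tuning is wavelength-independent with the peak at
`f_opt = 1/(2πτ)` — all enforced as tests.

The fit evaluates the model at the data's (λ, υ) conditions for every τ
on a grid (default 10–70 ms in 1.2 ms steps, endpoints inclusive → 51
values, with an exclusive-endpoint option since both conventions appear
in practice), normalizes each wavelength's model curve to its own
maximum magnitude, and accumulates the sum of squared differences
against the (already normalized) measured curve (a mean-squared option
exists; the choice is recorded in the fit object). Ties in the argmin go
to the smaller τ. The flat band is the contiguous grid run around the
minimum within 0.008 of the minimum LSE, mirroring how such fits'
sensitivity is usually quoted. Fitting is per wavelength by default;
pooling across wavelengths is a flag. Degenerate (constant) data are
flagged unidentifiable rather than fitted.

## Synthetic data: what it emulates, and what it does not

- **Eye generator.** Visual axes on a jittered hexagonal lattice over a
  spherical cap, rescaled about the cap center so the realized mean
  Delaunay-neighbor angle hits the target exactly (jitter would otherwise
  inflate it); the realized SD of the pairwise angles is of the right
  order but not calibrated. Lens centers sit on a sphere of radius
  `D/Δϕ` (radians) so adjacent lenses tile without overlap; markers are
  built deterministically from each axis and diameter, with isotropic
  Gaussian noise added last; the ocelli triangle is emitted in canonical
  pose. Real eyes have smooth dorsoventral gradients in D, l and Δϕ; the
  generator matches first moments only, which is sufficient for
  recovery testing but not for studying regional inhomogeneity.
- **Walk generator.** Optional initial wall-following span glued to the
  container circumference, a low-curvature random walk until onset
  (latency ~ N(1.76 s, 1.0 s) truncated at zero), circling at the signed
  ground-truth velocity on a circle through the entry point (pulled
  inside the container if needed), optional terminal rest bout, Gaussian
  position noise last. Defaults: 68 s at 60 Hz in a 15 mm container. The
  pre-onset "seemingly stationary" behavior of real animals is not
  quantitatively characterized anywhere; the random walk is a stated
  stand-in, adequate for latency- and filter-testing only.
- **Tuning generator.** Noise of SD `noise_sd` is added on the
  normalized-response scale, then each replicate's per-wavelength curve
  is renormalized to its own maximum — mirroring per-experiment
  normalization of measured data. This renormalization slightly biases
  condition means low near the peak (dividing by a noise-inflated
  maximum), which is a property of the measurement procedure itself and
  is kept.

All generators draw from a single explicit seed and restore the caller's
RNG state. Passing tests on these fixtures demonstrates correctness of
the estimators under the stated noise models — not robustness to real
tracking artifacts (occlusions, identity swaps) or real anatomical
digitization ambiguity.

## Numerical choices

- Arccosine arguments are clamped to [−1, 1].
- Circle fits use the linear Kasa parameterization; plane fits use SVD;
  the sphere center for the eye-cap projection is a linear least-squares
  fit, with a plane-projection fallback for coplanar layouts.
- Peak detection uses topographic prominence with plateaus reporting
  their first sample; `< 2` peaks yields an empty period list flagged
  `no_rotation`, not an error.
- `h = 0` (flat lens surface) propagates as a zero-curvature term; a
  non-positive lens power is a diverging-lens error with diagnostics.
- Grid-fit ties break toward smaller τ for determinism.

## Problem sizes used in the test suite

Synthetic eyes of 60 ommatidia; 68 s walks at 60 Hz; tuning datasets of
7 velocities × 20 replicates; τ-recovery sweeps over 50 seeds at three
ground-truth time constants; the dense temporal-frequency grid for peak
location uses 1 mHz steps over 0.1–20 Hz. The full suite runs in well
under a minute on one CPU.

## Limitations

- No wave optics: the acceptance angle is the geometric ratio d/l, with
  no diffraction or Gaussian point-spread treatment.
- No spatio-temporal EMD array simulation; only the closed-form
  steady-state expression.
- The τ fit is a grid search by design; no gradient or Bayesian
  estimation.
- Published eye-level means for real material (radii, focal length,
  acceptance angle) cannot be regenerated exactly from other published
  means because the underlying per-ommatidium data are not deposited;
  the package targets such quantities through parameter-recovery
  properties on synthetic data instead.
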