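# optomotor

Analysis pipeline for walking optomotor experiments on miniature insects
with highly reduced compound eyes (tens of ommatidia rather than
thousands). The package covers the full chain from anatomy to model:

1. **Eye geometry** — reconstruct per-ommatidium lens diameter *D*, visual
   axes and interommatidial angles Δϕ from digitized 3-D landmark tables
   (lens tips, six lens-base points, rhabdomere tip, plus three ocelli
   defining the head frame).
2. **Lens optics** — radii of curvature of the spherical corneal dome,
   `r = (D²/4 + h²) / (2h)` with *h* the lens half thickness; thin-lens
   focal length from the lens-maker formula,
   `1/l = (n_L − n_A)/r_air − (n_L − n_C)/r_cone`
   (lens *n*_L = 1.45, air *n*_A = 1, crystalline cone *n*_C = 1.35);
   geometric acceptance angle `Δρ = d / l` with *d* the rhabdomere spacing.
3. **Behavior** — score the optomotor response from rotating-drum walking
   trajectories: quality filters (wall-following > 3 s; total walk time
   < 10 s), full-rotation periods Δt from the peaks of the y-position
   trace, response `R = 360°/Δt` signed by co-/counter-rotation,
   per-experiment normalization, and tuning-curve assembly over
   (wavelength λ, drum velocity υ) conditions.
4. **EMD model** — closed-form steady-state response of a Reichardt
   correlation-type elementary motion detector to a drifting grating:

   `R_EMD = (1 + x²)^(-1/2) · sin(arctan x) · sin(2πΔϕ/λ) · (1 + (Δρ/λ)²)^(-1/2)`,
   `x = 2πτυ/λ`,

   with low-pass, temporal-frequency, interference (spatial-aliasing) and
   optics factors. Its temporal tuning peaks at `f_opt = 1/(2πτ)` and its
   wavelength tuning at `λ_max = 4Δϕ`.
5. **Time-constant fitting** — grid-search least squares of the low-pass
   time constant τ (10–70 ms, 1.2 ms steps) against normalized tuning
   curves, with the flat sensitivity band around the minimum.
6. **Synthetic data** — generators for eye landmark sets, walking
   trajectories and tuning-curve datasets with known ground truth, so
   every stage is testable without microtomography or video data.

## Worked example

```r
library(optomotor)

## anatomy: synthetic eye with 0.1 um landmark noise, reconstructed
eye   <- generate_synthetic_eye(synthetic_eye_spec(n_ommatidia = 60,
                                                   marker_noise_sd = 0.1,
                                                   seed = 42))
model <- reconstruct_eye(eye$markers, axis_method = "normal")
io    <- interommatidial_angles(model)
#> mean IO angle: 17.9 +/- 4.7 deg (N = 161 edges)

## behavior: one trajectory circling at 120 deg/s under a 60 deg grating
walk <- generate_walk_trajectory(synthetic_walk_spec(turning_velocity = 120,
                                                     position_noise_sd = 0.1,
                                                     seed = 42))
score_trajectory(walk, stimulus_condition(60, 210))
#>   wavelength velocity R_thrips n_periods onset_latency ...
#> 1         60      210      120        20          3.15 ...

## model: recover the EMD time constant from noisy tuning curves
dat <- generate_tuning_dataset(synthetic_tuning_spec(tau_true = 0.041,
                                                     seed = 42))
grid_fit_tau(tuning_means(dat), io_angle = 17.8, acceptance_angle = 17.7)
#> EMD time-constant grid fit: tau = 41.2 ms (LSE = 0.00183, sum over 7 conditions)
#>   flat band (+tol): 37.6-43.6 ms; implied f_opt = 3.86 Hz
```

The reconstructed mean interommatidial angle (17.9°) matches the
generator's 17.8° target; the scored turning velocity equals the
generating 120 deg/s; and the grid fit returns the grid point nearest the
41 ms ground truth, with the implied optimal temporal frequency
`1/(2πτ)` ≈ 3.9 Hz. A 17.8° interommatidial angle predicts maximal
motion-detector output at `λ_max = 4Δϕ = 71.2°`.

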