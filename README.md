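# hemoflow4d

Haemodynamic quantification for 4D-flow cardiac MR, with synthetic
pulsatile phantoms for end-to-end validation.

4D-flow CMR (time-resolved three-directional phase-contrast MRI) measures a
blood-velocity vector in every voxel at every cardiac frame. Postoperative
comparisons of surgical strategies in obstructive hypertrophic
cardiomyopathy — septal myectomy with and without anterior mitral valve
leaflet extension — rest on quantities derived from such fields: aortic
wall shear stress (WSS), LVOT peak velocity, kinetic energy (KE) density in
the LVOT and ascending aorta, transvalvular forward/backward flow,
simplified-Bernoulli gradients and LVOT longitudinal strain. This package
implements that measurement chain for analysts working with velocity-field
data, and, since clinical scans are rarely shareable, a phantom generator
that makes the whole chain testable against closed forms.

**The measurement chain**: temporal velocity anti-aliasing (venc
wrap-around), background phase-offset correction against static tissue,
3-D phase-contrast angiogram (PC-MRA) construction, threshold segmentation
and wall-surface extraction, peak-systole detection (first-half argmax of
mean left-ventricular speed), and the metrics:

- WSS: velocity sampled along inward wall normals, quadratic no-slip fit,
  τ = μ ∂v_t/∂n, area-weighted mean magnitude (Pa);
- peak velocity: max voxel speed in the mask (m/s);
- KE density: mask mean of ½ρ|v|² at peak systole (printed mJ/m³ scale);
- transvalvular flow: Q(t) = ∮ v·n̂ dA over a tracked valve plane, forward
  and backward volume per beat (ml);
- ΔP = 4v² (mmHg), max and systolic mean; strain from contour lengths (%).

**The phantom**: quasi-steady power-law tube flow
v(r,t) = v_max(t)(1 − (r/R)ⁿ) on the emulated acquisition grid
(2.4 × 2.4 × 2.5 mm, 24 frames), with exact closed forms
τ_w = μ n v_max/R, KE = ½ρv_max² g(n) with g(n) = 1 − 4/(n+2) + 1/(n+1),
and Q = πR² v_max n/(n+2). Corruptions (Gaussian velocity noise, polynomial
phase offsets, venc wrapping) are applied after the analytic truth is
recorded. `calibrate_segment()` inverts the closed forms so cohorts of
phantoms realise published group means exactly; `make_cohort()` builds the
three 3-subject study arms.

## Worked example

Calibrate an aortic segment to a target (WSS 0.73 Pa, KE 480.8), generate a
corrupted phantom, preprocess, and measure:

```r
library(hemoflow4d)
cfg <- analysis_config()                     # mu 0.0032 Pa s, rho 1060 kg/m3

cal <- calibrate_segment(0.73, 480.8, 0.0125, cfg)
# vmax = 1.857 m/s, n = 1.535

ph <- make_tube_phantom(phantom_spec(
  radius = 12.5, profile_exponent = cal$n,
  vmax_waveform = cal$vmax * systolic_waveform(),
  noise_frac = 0.02, alias = TRUE, seed = 7), cfg)

pp    <- preprocess_field(ph$field, cfg, static_mask = ph$masks$static_tissue)
frame <- find_peak_systole(pp$field, ph$masks$lv)        # frame 6
surf  <- extract_wall_surface(ph$masks$aorta, ph$field$spacing,
                              flow_mask = ph$masks$lumen)
compute_wss(pp$field, frame, surf, cfg)
#> <wss_field> 896 points, area-weighted mean 0.749 Pa (0 skipped)
kinetic_energy_density(pp$field, frame, ph$masks$aorta, cfg)
#> 488.6                                      # analytic truth: 480.8
transvalvular_flow(pp$field, hemoflow4d:::inlet_track(ph))
#> <flow_result> forward 66.6 ml, backward 0.7 ml per beat   # truth: 66.0 ml
```

The measured WSS (0.749 Pa vs 0.73 target), KE (488.6 vs 480.8) and forward
volume (66.6 vs 66.0 ml) show the pipeline recovering the analytic truth to
a few percent through noise, offsets and wrap-around.

## Analysis workflow

Numbered drivers under `analysis/` run the full study on synthetic cohorts
and write tables under `results/`:

```sh
Rscript analysis/01_simulate_cohorts.R    # 3 groups x 3 subjects + truth.csv
Rscript analysis/02_preprocess.R          # corruption-recovery check
Rscript analysis/03_segmentation_timing.R # Dice, surface area, peak frames
Rscript analysis/04_hemodynamics.R        # per-subject metrics vs truth
Rscript analysis/05_cohort_report.R       # group table + percent differences
```

The final report (`results/report/cohort_table.csv`, `.md`) carries group
mean ± SD, 95% t-intervals and percent differences against the
isolated-myectomy reference.

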