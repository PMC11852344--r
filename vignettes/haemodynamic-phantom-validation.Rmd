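---
title: "Haemodynamic quantification for 4D-flow CMR: model, phantoms and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haemodynamic quantification for 4D-flow CMR: model, phantoms and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemoflow4d)
```

## The problem

Time-resolved three-directional phase-contrast MRI (4D-flow CMR) measures a
blood velocity vector in every voxel of the heart and great vessels at every
cardiac frame. From such a field, clinically interpreted quantities are
derived: wall shear stress (WSS) on the vessel wall, peak velocity and
kinetic energy (KE) density in the left ventricular outflow tract (LVOT) and
ascending aorta, forward and backward volume across the aortic and mitral
valves, simplified-Bernoulli pressure gradients, and longitudinal strain.
This package implements that chain of computations, and — because clinical
scans are rarely shareable — a synthetic pulsatile tube-flow phantom
generator whose every output quantity has a closed form, so the whole
pipeline can be validated end to end against analytic truth and calibrated
cohorts can be built whose true group means equal published group tables.

## The flow model

The phantom is quasi-steady power-law tube flow. Inside a straight tube of
radius $R$, the axial velocity at radial distance $r$ and frame $t$ is

$$v(r, t) = v_{\max}(t)\,\bigl(1 - (r/R)^n\bigr), \qquad n \ge 1,$$

zero outside. The shape exponent $n$ is fixed over the cycle and only the
centreline amplitude $v_{\max}(t)$ is modulated. $n = 2$ is parabolic
(Poiseuille) flow; large $n$ approaches plug flow. This is deliberately not
a Womersley (oscillatory Navier–Stokes) solution: the quasi-steady profile
keeps every target quantity in closed form,

$$\tau_w = \mu\,n\,v_{\max}/R, \qquad
  \overline{KE} = \tfrac12 \rho\, v_{\max}^2\, g(n), \qquad
  g(n) = 1 - \tfrac{4}{n+2} + \tfrac{1}{n+1}, \qquad
  Q = \pi R^2 v_{\max} \tfrac{n}{n+2},$$

which is exactly what an estimator oracle needs. The price is that no
secondary flow, curvature or unsteady boundary-layer physics is represented;
passing tests show metric correctness on resolved laminar tube flow, not
fidelity to intracardiac flow patterns.

Two free parameters $(v_{\max}, n)$ meet two targets: `calibrate_segment()`
inverts $(\tau_w, \overline{KE}) \mapsto (v_{\max}, n)$ by bisection on the
strictly decreasing $g(n)/n^2$, and the LVOT variant fixes
$v_{\max}$ = the peak-velocity target and solves $g(n)$ for the KE target.
The decoupling of peak velocity from KE through $n$ is what makes both
columns of a published group table matchable simultaneously.

```{r calibration}
cal <- calibrate_segment(0.73, 480.8, 0.0125)   # aortic WSS (Pa), KE, R (m)
unlist(cal)
poiseuille_wall_shear(cal$vmax, 0.0125, 0.0032, cal$n)
```

One physical corner deserves note: the healthy-control aortic pair
(WSS 0.47 Pa with KE 345.4) requires $g(n)/n^2 = 0.193 > g(1) = 1/6$ at a
12.5 mm radius — no exponent $n \ge 1$ exists. Low wall shear together with
high kinetic energy implies a wider vessel. `make_cohort()` therefore grows
the segment radius to 1.1 × the minimal feasible radius (≈ 14.8 mm here)
when needed; `calibrate_segment()` itself refuses infeasible targets with an
error naming the bound.

## Acquisition model

Defaults mirror the emulated protocol: in-plane resolution 2.4 × 2.4 mm,
slice thickness 2.5 mm, 24 cardiac frames over a 1000 ms cycle (≈ 42 ms
temporal resolution), velocity encoding limit (venc) 2.0 m/s — chosen above
the largest calibrated peak velocity, as a scan operator would. Corruptions
are applied in the physical order of acquisition:

1. **Noise**: independent zero-mean Gaussian per velocity component,
   SD = `noise_frac` × venc (the standard phase-contrast noise model;
   cohort default 0.02).
2. **Background phase offset**: a second-order spatial polynomial per
   component, constant in time, as eddy-current offsets are to first order.
3. **Aliasing**: wrap-around into $(-\mathrm{venc}, \mathrm{venc}]$ by
   multiples of 2 venc.

The truth record is computed from the closed forms *before* corruption, so
it is independent of the noise seed.

Two geometric choices matter and were made once, from a discretization
study, before the cohorts were frozen:

* **The tube axis is oblique to the grid** (default ≈ 10°, with per-subject
  sub-voxel centre jitter in cohorts). A grid-aligned tube gives every slice
  the same sub-voxel alignment, and the WSS estimate then swings ±10–15%
  with that alignment; an oblique tube samples all alignments along its
  length and the swing collapses to 1–3%. Real vessels are oblique to
  scanner axes, so this is realism, not a trick — but it means the
  "SD = 0" degenerate cohort produces subjects with identical *truths*, not
  bit-identical fields.
* **The segment mask is shorter than the flow channel.** Flow runs through
  the whole volume; the analysis mask covers an interior slab. Surface
  extraction takes the full lumen as `flow_mask` so that the open inlet and
  outlet cross-sections are not treated as walls — an aortic "wall" face
  with purely through-plane flow would dilute mean WSS toward zero.

## Measurement pipeline and numerical choices

**Anti-aliasing** is temporal-only: each voxel/component series is scanned
in frame order and any jump exceeding venc is closed by the multiple of
2 venc that minimises it (a tie at exactly venc is left alone). It is
idempotent, and exact whenever the first frame is unwrapped and true
frame-to-frame changes stay below venc — both hold for cardiac waveforms
sampled at 24 frames.

**Offset correction** fits the second-order polynomial to static-tissue
velocities per frame by least squares, averages coefficients over frames
(offsets are temporally stable), and subtracts the fitted field everywhere.
Static tissue is detected where temporal speed SD *and* mean are below
`static_sd_frac` × venc (default 0.05); supplied static masks take
precedence — note that a constant offset of 0.05 m/s per component already
pushes static mean speed (√3 × 0.05 ≈ 0.087 m/s) past the detection
threshold at venc 1.5, which is exactly why the pipeline prefers supplied
masks. Coplanar static voxels make the quadratic terms unidentifiable; the
fit then falls back to a constant with a warning.

**PC-MRA and segmentation.** The angiogram is the time average of
magnitude × speed. Threshold segmentation (fraction of maximum, largest
26-connected component) reproduces the lumen only for blunt profiles: at
half-maximum a parabolic profile keeps $r \le R/\sqrt2$ (Dice ≈ 0.67) by
construction. The threshold tool is therefore a stand-in for manual
segmentation on plug-like flows, and cohort analyses use the supplied
masks.

**Wall surface.** Surface points start at exposed voxel-face centres (the
0.5 iso-surface of the binary mask) and are Newton-projected onto the 0.5
level set of the Gaussian-smoothed mask (σ = 2.8 mm), then shifted outward
by $\sigma^2 \kappa / 2$ — the level-set erosion a convex shape suffers
under smoothing, with total curvature κ estimated from the divergence of
the normal field. This cuts point-placement scatter from ±0.65 mm to
±0.26 mm and keeps the mean radius error below 0.1 mm; displacements are
capped at one voxel so points stay on the digital boundary. Face weights
$A_{face}\,|\hat n \cdot \hat e|$ sum to the analytic area within ~2% at
study resolution.

**WSS estimation** samples velocity by trilinear interpolation at
`wss_sample_distances` along the inward normal, removes the normal
component, and fits $v(d) = a d + b d^2$ through the origin (no-slip) by
least squares; the WSS vector is $\mu a$ per tangential component and the
summary is the area-weighted mean magnitude. The sample distances are the
critical tuning parameter on a 2.4 mm grid and were set from a bias study
over the study's radius/exponent regime, not per target:

* at {0.6, 1.2} mm (¼, ½ voxel) the first sample sits half a voxel from the
  wall where trilinear interpolation is dominated by zero-filled exterior
  voxels: +35–70% bias;
* at {1.2, 2.4} mm the near-wall bias and the trilinear concavity error
  roughly cancel (noise-free bias ≤ 3% across regimes), but under the study
  noise level the per-point scatter inflates the mean *magnitude* where WSS
  is low (up to +8% on the healthy aorta);
* the default {1.2, 1.8, 2.4} mm three-point least squares keeps the
  noise-free oracle within −5% and the noisy cohort bias within +6%
  everywhere.

The residual, honestly stated: at this resolution the estimator is accurate
to roughly ±5%, and its noise-induced component is a *positive* bias
(magnitudes of noisy vectors average above the clean magnitude).

**Peak velocity** is the single maximum voxel speed in the mask — no
percentile robustification, because the quantity is a peak. Under the study
noise level (SD 0.04 m/s per component) the maximum over ~10³ lumen voxels
is biased up by ≈ +0.08 m/s; at 1.25 m/s that is ≈ +6%. This is a property
of the definition, accepted and visible in the validation numbers.

**KE density** is the mask mean of $\tfrac12\rho|v|^2$, evaluated at the
peak-systolic frame (not a maximum over frames). Values are computed in
J/m³ and reported numerically on the clinical "mJ/m³" convention — the
published magnitudes are consistent with mJ/L ≡ J/m³, and the package
follows the printed scale without resolving the unit inconsistency.

**Peak systole** is the frame with the highest mean speed in the LV mask
within the first half of the cycle, frames 1..⌈T/2⌉ (1-based), earliest
frame on ties.

**Transvalvular flow** resamples the through-plane component on a uniform
grid over the aperture disc (spacing ≤ half the smallest voxel dimension),
with each sample carrying an equal share of the true disc area — so uniform
plug flow reproduces $vA$ exactly and quadrature error on smooth profiles
stays below 1%. Velocities outside the lumen contribute their near-zero
values; no lumen masking is applied at the plane.

**Bernoulli and strain.** $\Delta P = 4 v^2$ (mmHg for m/s, the clinical
convention; no Pa intermediate); the maximum uses the highest systolic peak
velocity and the mean is the systolic time-average of instantaneous
$4v^2$ — the "mean gradient" is not otherwise defined in routine practice.
Strain is length-based: $(\min_t L(t) - L(1))/L(1) \times 100$ over a
supplied contour-length series; the commercial feature-tracking algorithm
that would produce such contours from cine images is out of scope.

## Cohort calibration

`make_cohort()` draws per-subject targets from the printed mean ± SD with
two deliberate departures from naive sampling:

* **Moment matching.** The three draws are centred and scaled so the cohort
  realises the printed mean and SD exactly. With n = 3 and SDs like
  1.63 ± 0.3 m/s, naive sampling leaves the *true* group mean itself with a
  ~10% standard error, which would swamp the pipeline error the validation
  is meant to measure. The generator's purpose is calibration, so the
  calibration is exact.
* **A latent severity factor.** One normalised deviation vector drives the
  per-subject peak-velocity, KE and WSS draws (stroke volumes get a second
  factor). Within a group these quantities co-vary with flow vigor;
  independently drawn pairs land outside the physically admissible region
  $g(n) \in [g(1), g(20)]$ in most triples.

Stroke-volume targets are met by shaping the waveform area at fixed
systolic peak: a raised-sine systolic lobe with solvable exponent, plus —
when the target exceeds what systole can carry at the calibrated peak
velocity (mitral 84 ml at 1.63 m/s through a 9.4 mm radius does) — a
flattened-sine diastolic forward lobe for the remainder. Peak-frame metrics
and Bernoulli gradients use only systolic frames and are unaffected.

Default radii: LVOT 9.4 mm (half the ~18.8 mm LVOT diameter typical of
these patients), ascending aorta 12.5 mm, grown per group when calibration
demands it (above).

## Validation scope and problem sizes

The test suite checks every operation against hand values or closed forms,
property-style invariants (idempotence, linearity in μ, rotation invariance
of KE, forward/backward swap under normal reversal, first-half restriction
of peak systole) and, end to end, recovery of the published group means by
3-subject calibrated cohorts at noise_frac 0.02 within 10%. Problem sizes —
tubes of 20–25 voxels across and 24 frames, three subjects per arm, the
arm sizes of the emulated study — keep a full cohort recovery under ten
seconds while leaving every discretization effect of the target resolution
in place. What passing does *not* show: fidelity on curved, branching,
turbulent or under-segmented anatomy, vendor-specific offset behaviour, or
valve-tracking errors — the plane tracks are inputs here.

## Known limitations

* Quasi-steady power-law flow only; no Womersley physics, no curvature.
* Temporal-only unwrapping: a voxel aliased already at frame 1, or a true
  inter-frame change above venc, defeats it.
* WSS accuracy (±5%) is specific to resolved tubes at 2.4 mm; clinical WSS
  at coarser effective resolution underestimates substantially.
* The peak-velocity noise bias (+≈0.08 m/s at the study noise level) is
  inherent to the max-voxel definition.
* Threshold segmentation is a stand-in; it tracks iso-velocity contours on
  non-blunt profiles.
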