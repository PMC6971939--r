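---
title: "Accelerated 4D flow MRI at desk scale: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accelerated 4D flow MRI at desk scale: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spiralflow)
```

## What the package models

4D flow cardiovascular MRI measures all three blood-velocity components in
every voxel of a 3D volume, resolved over the cardiac cycle. Because a fully
sampled, retrospectively gated, four-point flow-encoded acquisition takes on
the order of an hour, practical protocols undersample k-space heavily and
recover the image series with a compressed-sensing (CS) reconstruction.
`spiralflow` implements one such acceleration strategy end to end at desk
scale:

1. **Trajectory design** — pseudo-spiral Cartesian sampling of the two
   phase-encode dimensions (k~y~, k~z~), with successive spiral arms rotated
   by a tiny golden angle;
2. **Acquisition simulation** — a digital pulsatile-vessel phantom with
   multi-coil, four-point flow-encoded k-space sampling and RR-interval
   variability;
3. **Retrospective cardiac binning** — "absolute" assignment of each readout
   to a cardiac frame from the R-top times;
4. **Reconstruction** — temporal total-variation (TV) regularized CS, next
   to a zero-filled linear baseline;
5. **Hemodynamics** — time-resolved flow rate, stroke volume, peak-systole
   detection and wall shear stress (WSS);
6. **Statistics** — Bland-Altman and orthogonal-regression comparison of
   runs at different acceleration factors.

Everything is generated in code; no scanner data is required. The synthetic
scene deliberately mirrors a pulsatile carotid-style flow-phantom bench
setup: a tube in a static bath, driven at 60 bpm with 5% RR variability,
peak inlet flow 10 ml/s and mean 3 ml/s, imaged with VENC 150 cm/s and
TR 8.9 ms.

## Sampling design

A pseudo-spiral arm follows the quadratic spiral law $r(\varphi) =
\varphi^2$ with $\varphi$ increasing linearly ("linearly increasing angle"
is read as uniform increments) from 0 to $2\pi l$ over $n$ readouts
(defaults $n = 100$, $l = 3$). The radius is normalized so the final sample
reaches the edge of the k~y~ grid ($m_{k_y}/2 - 1$ grid units); for
asymmetric matrices the k~z~ coordinate is scaled by the matrix aspect ratio
$(m_{k_z}/2)/(m_{k_y}/2)$ before rounding. Points are rounded to the nearest
Cartesian grid location (ties toward zero) and clamped symmetrically to
$\pm(m/2 - 1)$; clamping rather than discarding keeps every arm at a
constant length of $n$ readouts, preserving the $n \cdot l$
parameterization. Duplicate grid points within an arm are kept in the
schedule — acquisition time is still spent on them — and merged by count at
binning.

Successive arms are rotated by a tiny golden angle, by default the order-7
member $180^\circ/(\tau + 6) = 23.63^\circ$ of the generalized golden-angle
sequence ($\tau$ the golden ratio); rotations accumulate and are reduced
modulo 360°. Small arm-to-arm rotation keeps k-space jumps short (the
hardware motivation) while the golden-ratio irrationality spreads arms
azimuthally, which yields the variable-density, densely-sampled-center
pattern that CS reconstruction favors. The quadratic radius law concentrates
samples near the k-space center; the package asserts this variable-density
property as a test invariant rather than any eddy-current behavior, which
is out of scope.

The acceleration factor is budgeted as $R = N_{\mathrm{fully}} /
N_{\mathrm{undersampled}}$ with $N_{\mathrm{fully}} = N_{k_y} N_{k_z}
N_{\mathrm{card}} N_{\mathrm{flow}}$. `build_schedule()` emits whole arms
until the readout budget $N_{\mathrm{fully}}/R$ is first reached, so the
realized R deviates from the target by at most one arm quantum. Each profile
expands to four consecutive flow-segment events (reference plus three
velocity encodings) before the profile advances, and acquisition time
advances one TR per event. Schedules export to a plain-text "ky kz" per-line
file, the format scanner-side prospective-undersampling patches import.

## Retrospective binning

Events are assigned to cardiac frames "absolutely": frame =
$\lfloor (t - t_{R\text{-top}}) / \Delta t \rfloor$ with a fixed frame
duration $\Delta t = \mathrm{RR}_{\mathrm{nominal}} / N_{\mathrm{card}}$,
not per-beat stretching. Events falling beyond frame $N_{\mathrm{card}}$ in
long beats are rejected rather than folded into the last frame. Under RR
variability the trailing (end-diastolic) frames systematically receive
fewer samples; they are therefore flagged (default: last 2 frames,
phantom-style; 3 is typical in vivo) and excluded from flow-curve
summaries, while remaining present in the reconstruction output. Duplicate
acquisitions of the same (profile, frame, segment) cell are averaged via
the sample-count companion of the k-t mask; the scanner-side bitmask that
would prevent them prospectively is not simulated. The effective
acceleration factor is recomputed retrospectively as the full index-set
size over the number of sampled cells, and is reported alongside the
target R (it is larger than the target whenever binning scatters repeats
onto already-sampled cells).

## The digital phantom

The scene is a rigid straight tube of radius $a$ (default 3 mm) along the
readout axis of an isotropic grid (default $8 \times 64 \times 64$ voxels
at 0.8 mm — the in-plane matrix and resolution of a carotid protocol,
scaled down in the readout direction and frame count to desk scale). The
ground-truth velocity field is an axial parabolic (Poiseuille) profile
$v(\rho, t) = 2Q(t)/(\pi a^2)\,(1 - \rho^2/a^2)$, which makes every
downstream quantity analytically checkable. A rigid tube replaces the
compliant bifurcation of a physical bench phantom precisely because oracle
testing needs closed-form truth.

The inlet waveform is constrained by peak (10 ml/s), cycle mean (3 ml/s)
and period (1000 ms); its shape is otherwise free and is chosen as a
raised-cosine systolic pulse on a diastolic baseline, with the pulse width
(default 300 ms, a physiological systolic duration) and peak time (150 ms)
fixed a priori and the baseline/amplitude solved exactly for the peak and
mean targets. RR intervals are independent Gaussians (mean 1000 ms, SD 5%,
truncated at ±3 SD). Coil sensitivities are smooth complex Gaussian lobes
around the phase-encode plane (default 4 coils, scaled down from 32- or
8-channel arrays).

Encoding follows the referenced four-point scheme: magnitude 1.0 in the
lumen over a 0.3 background (the contrast exercises partial-volume effects
at the wall), phase $\pi v_d / \mathrm{VENC}$ for segment $d$, zero for
the reference. Per event the velocity field is evaluated at the event's
phase within its current simulated beat — RR variability therefore
produces genuine intra-frame blur — the image is weighted by each coil
map, and the orthonormal 2D DFT sample at the event's (k~y~, k~z~) is
recorded for every readout position, plus i.i.d. complex Gaussian noise
(default SD 0.02 of the lumen magnitude). For speed, event times are
quantized within the cycle to 64 levels (~16 ms at 60 bpm, well below a
52–100 ms frame) so scene DFTs are shared; `time_quantization = 0` gives
exact per-event evaluation.

What the phantom does **not** model: wall compliance and motion, Womersley
(inertial) velocity profiles, turbulence, in-flow enhancement and T1
saturation, eddy-current or concomitant-field phase offsets, and
respiration. Passing tests therefore demonstrate correctness of the
pipeline's mathematics under idealized flow, not robustness to those
physical effects; in vivo behavior (e.g. the stronger underestimation of
peak flow seen against 2D references) is outside what these tests can
show.

## Reconstruction

Per flow segment the solver approximately minimizes

$$\hat m = \arg\min_m \tfrac12 \lVert F_U m - y \rVert_2^2 +
\lambda\, \mathrm{TV}_t(m),$$

with $F_U$ the coil-weighted undersampling Fourier operator and
$\mathrm{TV}_t$ the $\ell_1$ norm of first-order temporal differences,
cyclic over the cardiac cycle (frames are periodic; spatial TV is not
used). Two deliberate numerical conventions: the data term is the
conventional squared $\ell_2$ (some formulations write an unsquared norm;
the squared form is what standard solvers minimize and what the package
reports), and the data are normalized so the zero-filled image peak is ~1,
which makes the default $\lambda = 0.01$ transferable across problem
scales.

The solver is ADMM on the split $z = D_t m$: the image update solves
$(A^H A + \rho D_t^H D_t)\,m = A^H y + \rho D_t^H(z - u)$ by warm-started
conjugate gradients (default 10 inner steps), the split update is complex
soft-thresholding, and the scaled dual ascends. Defaults $\lambda = 0.01$
and 10 outer iterations; the penalty $\rho = 0.1$ and the CG depth control
convergence rate only (every $\rho$ targets the same minimizer) and were
chosen so the iterate is near-converged within the 10 outer iterations.
The true objective is recorded each outer iteration and is checked
(non-increasing) in the test suite. Initialization is the zero-filled
image: the adjoint of $F_U$ with count-averaged duplicates followed by
sensitivity-weighted coil combination, which also serves as the linear
comparison baseline. Coil maps are the known simulation maps; no
self-calibration is attempted.

Velocities decode voxel-wise as $v_d = \arg(m_d \bar m_{\mathrm{ref}}) /
\pi \cdot \mathrm{VENC}$, wrapping into $(-\mathrm{VENC}, \mathrm{VENC}]$.
An optional static-tissue phase-offset correction (first-order 3D
polynomial fitted to the time-averaged velocity of static voxels, then
subtracted) is provided but off by default: the simulator introduces no
offsets, so in synthetic runs it would only fit noise.

## Hemodynamics

Flow rate integrates the **through-plane** velocity component over an ROI
cross-section, $Q(t) = \sum v_\perp \cdot \Delta A$. Integrating the speed
instead would be positively biased for any noisy or recirculating flow and
inconsistent with 2D flow practice, so the through-plane convention is
used even where method descriptions loosely say "absolute velocity". Peak
systole is the non-discarded frame with the highest mean speed inside the
segmented lumen (ties resolve to the earliest frame). Stroke volume is the
rectangle-rule integral of the flow curve over non-discarded frames; the
package reports SV and paired SV differences directly rather than naming
any particular published error metric whose exact formula lives elsewhere.

WSS uses $\tau = 2\eta\,\dot\varepsilon\,n$ with
$\eta = 3.2\times10^{-3}$ Pa·s, evaluated in a local frame whose $z'$ axis
is the inward wall normal; with no through-wall flow this reduces to
$\tau = \eta\,(\partial v_{x'}/\partial z', \partial v_{y'}/\partial z',
0)$. The wall is extracted from the binary lumen mask as one surfel per
lumen/background face at the 0.5 iso-level; inward normals come from the
gradient of a Gaussian-smoothed (σ = 1.2 voxels) copy of the mask, which
on a digitized cylinder recovers radial normals to well under 5°. Grid
boundaries are treated as open ends, not wall. Tangential velocities are
sampled at k = 4 points spaced one voxel along the inward normal by
trilinear interpolation, the wall sample is clamped to zero (no-slip), and
the derivative at the wall is taken from a least-squares quadratic
through the origin — a single-segment smoothing fit that is exact on both
linear shear and parabolic profiles. The local $x'$ axis is built
deterministically from the global axis with the smallest normal component.
Points whose sampling ray leaves the grid are excluded and counted. On the
default 0.8 mm grid, the digitized Poiseuille tube recovers the analytic
wall shear $4\eta Q/(\pi a^3)$ to about −5%; the test suite allows 15% to
cover discretization across geometries.

Cross-run comparisons pair WSS values by nearest reference wall point
(pairs beyond 2 voxels are dropped and counted) and velocities voxel-wise
on the shared lumen grid. Synthetic runs share geometry exactly, so the
rigid registration a physical study needs is the identity here.

## Statistics and the sweep driver

Bland-Altman reports the mean difference (test − reference), its SD and
the 1.96·SD limits of agreement; percent differences use the grand mean of
the pair averages as denominator (the standard relative-BA convention;
when the grand mean is zero the percentage is undefined and reported NA).
Orthogonal regression is classic total least squares with equal error
variances — the slope follows the major principal axis of the 2×2
covariance — plus the conventional Pearson ρ.

`run_experiment()` drives the whole pipeline once per acceleration factor
on a shared scene and compares every run against the lowest-R reference.
On the default desk-scale conditions (matrix 8 × 64 × 64, 10 frames,
R ∈ {2, 10, 20}, seed 1) the sweep reproduces the expected qualitative
behavior — velocity-vs-reference Pearson ρ non-increasing in R, limits of
agreement widening, hemodynamic magnitudes drifting down with R — which
the acceptance tests assert as orderings, not as magnitudes: headline
percentages from scanner studies of physical phantoms and volunteers are
not reproducible from a synthetic desk-scale scene, and the package makes
no claim to them.

## Problem sizes and runtime

The package's own quantitative checks run at: $8\times64\times64$, 10
frames, 4 coils, R = 10 for the reconstruction-quality comparison; the
same scene at R ∈ {2, 10, 20} for the trend sweep; and
$4\times16\times16$ scenes for solver unit tests. These sizes were chosen
so a full check runs on one CPU core in minutes while keeping the in-plane
resolution (0.8 mm) and the undersampling regime of a real carotid
protocol.

## Known limitations

- Rigid, straight, single-vessel geometry; no bifurcation, stenosis or
  wall motion.
- The waveform shape beyond peak/mean/period is a package choice; bench
  phantoms with sharper systolic peaks will stress temporal TV harder
  than this raised-cosine pulse does.
- Coil maps are known to the reconstruction (no calibration error).
- The CS solver covers temporal TV only; low-rank or wavelet priors and
  parallel-imaging calibration are out of scope.
- Phase wraps beyond VENC are produced faithfully by the simulator but no
  unwrapping is attempted at decoding.
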