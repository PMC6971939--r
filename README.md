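# spiralflow

Accelerated 4D flow MRI at desk scale: pseudo-spiral Cartesian k-t
sampling design, retrospectively gated acquisition simulation on a
digital pulsatile vessel phantom, temporal-total-variation
compressed-sensing reconstruction, and quantitative flow-rate / wall
shear stress analysis with Bland-Altman comparison across acceleration
factors.

## Who this is for

Researchers developing or validating accelerated 4D flow cardiovascular
MRI protocols who want a fully synthetic, reproducible testbed: every
input (vessel geometry, inlet waveform, heart-rate variability, coil
sensitivities, k-space noise) is generated in code with analytic ground
truth, so reconstruction and hemodynamic-analysis errors can be measured
exactly rather than estimated against another scan.

## The method in brief

**Sampling.** Phase-encode profiles (k_y, k_z) follow a pseudo-spiral on
the Cartesian grid, r(φ) = φ² with φ linearly increasing over l = 3 turns
and n = 100 readouts per arm; successive arms rotate by the tiny golden
angle 180°/(τ+6) = 23.63°. The acceleration factor is budgeted as

    R = N_fully / N_undersampled,   N_fully = N_ky · N_kz · N_card · N_flow

and whole arms are emitted until the readout budget is met. Continuous
profile updating through the cardiac cycle plus retrospective "absolute"
binning (fixed frame duration from the nominal RR) yields incoherent,
variable-density k-t sampling masks with a densely sampled center.

**Reconstruction.** Per flow segment,

    m̂ = argmin_m  ½‖F_U m − y‖₂² + λ · TV_t(m)

with F_U the coil-weighted undersampling Fourier operator and TV_t the
l1 norm of cyclic first-order temporal differences; λ = 0.01 on
peak-normalized data, 10 outer ADMM iterations with an inner-CG image
update. Velocities decode from referenced four-point phase differences,
v = arg(m_d · conj(m_ref))/π · VENC.

**Hemodynamics.** Q(t) integrates through-plane velocity over an ROI
plane; wall shear stress is τ = η (∂v_x'/∂z', ∂v_y'/∂z', 0) in a local
frame aligned with the inward wall normal (η = 3.2·10⁻³ Pa·s), with
spline-style derivative fits along the normal. Runs at different R are
compared voxel-wise with Bland-Altman statistics and orthogonal (total
least squares) regression.

## Worked example

A full synthetic sweep over acceleration factors R = 2, 10, 20 on the
default scene (8 × 64 × 64 voxels at 0.8 mm, 3 mm tube, 60 bpm ± 5%,
peak/mean inlet flow 10/3 ml/s, VENC 150 cm/s, 4 coils, 10 cardiac
frames), about 6 minutes on one core:

```r
library(spiralflow)
report <- run_experiment(experiment_config(R_values = c(2, 10, 20), seed = 1))
report$table[, c("R_target", "effective_R", "peak_q_mlps",
                 "peak_velocity_cmps", "mean_wss_pa", "vel_rho",
                 "vel_loa_width", "wss_mean_diff_pct")]
```

```
  R_target effective_R peak_q_mlps peak_velocity_cmps mean_wss_pa vel_rho vel_loa_width wss_mean_diff_pct
1        2       4.253       8.836              68.54       1.286  1.0000          0.00             0.000
2       10      14.689       8.443              67.33       1.209  0.9749         17.79            -6.205
3       20      27.180       8.096              61.83       1.132  0.9565         24.18           -12.779
```

Reading the table: the analytic peak flow is 10 ml/s and the analytic
peak velocity 70.7 cm/s; frame binning (10 frames over a 300 ms systolic
pulse) and voxel discretization alone account for most of the gap at
R = 2. As R grows, the voxel-wise velocity correlation against the R = 2
reference (`vel_rho`) decreases, the Bland-Altman limits of agreement
(`vel_loa_width`, cm/s) widen, and mean WSS differences
(`wss_mean_diff_pct`) grow more negative — the same qualitative behavior
reported for scanner studies of accelerated 4D flow. `effective_R`
exceeds the target because retrospective binning lands repeated profiles
on already-sampled k-t cells.

Single pieces are usable on their own, e.g. exporting a scanner-ready
profile list:

```r
sch <- build_schedule(spiral_params(160, 40),
                      acceleration_spec(160, 40, N_card = 19, R_target = 10))
export_profiles(sch, "profiles.txt")
```

or from the shell:

```sh
Rscript inst/cli/spiralflow.R design --matrix 160x40 --frames 19 --R 10 --out profiles.txt
```

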