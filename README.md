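# csfflow

Quantification of cardiac-cycle-linked cerebrospinal fluid (CSF) flow from
cardiac-gated phase-contrast MRI (PC-MRI), at the Sylvian aqueduct or the
cranio-cervical junction (CCJ). For researchers post-processing gated phase
series with hand-drawn regions of interest (ROIs) who need per-pixel
velocities turned into defensible flow metrics.

## What it computes

Given a gated phase series (one 2-D frame per cardiac phase), a lumen ROI
and a reference ROI in adjacent static tissue, the pipeline applies, in
order:

1. **Velocity conversion** — the linear PC-MRI map
   `v = raw × VENC / raw_scale` (cm/s);
2. **Aliasing correction** — temporal unwrapping per pixel: velocities that
   wrapped past ±VENC are restored by shifting samples by multiples of
   2·VENC, anchored at the cardiac phase with the smallest ROI-mean
   absolute velocity;
3. **Bias subtraction** — the reference ROI's mean velocity estimates the
   static eddy-current phase offset shared by CSF and tissue, and is
   subtracted from the CSF velocities; its spread doubles as a noise
   estimate for SNR screening.

From the corrected velocities `v_i` it forms the volumetric flow curve and
its cycle integral (pixel area `dx·dy`, frame spacing `dt = T/n`):

```
Q(t)  = ( Σ_i v_i(t) ) · dx · dy                      [mL/s]
SV    = (dt/2) Σ_i ( Q(t_{i+1}) + Q(t_i) ),  Q(t_{n+1}) ≡ Q(t_1)
```

plus antegrade/retrograde volumes (integrals of the negative/positive
parts of Q), net flow per cycle, per minute (`× HR`) and per day
(`× HR × 1440`), and a direction label (aqueduct: negative = antegrade,
3rd→4th ventricle; positive = retrograde; CCJ: positive = upward).

A built-in phantom simulator generates gated acquisitions with exact ground
truth — circular lumen, plug or Poiseuille profile, pulsatile waveform,
shared baseline offset, Gaussian noise, optional wrapping — so every stage
is testable without scanner data. Cohort utilities aggregate per-subject
metrics into direction counts/proportions, subgroup mean ± SD summaries and
net-flow-versus-volume Pearson correlations.

## Worked example

```r
library(csfflow)

truth <- flow_ground_truth(profile = "parabolic",
                           mean_velocity_offset = 0.3,  # cm/s, toward head
                           pulsatile_amplitude = 3,     # cm/s
                           baseline_offset = 1.2,       # shared eddy bias
                           noise_sd = 0.5)              # cm/s
sim <- simulate_acquisition(truth, seed = 42)
res <- quantify_flow(sim$series, sim$target, sim$reference)
res$metrics
#> flow_metrics (aqueduct, 26 px, HR 70 bpm)
#>   net: 0.01161 mL/cycle = 0.8124 mL/min = 1.17 L/day (retrograde)
#>   antegrade -0.03375 mL, retrograde 0.04536 mL, stroke volume 0.01161 mL
sim$truth$true_net_mL_per_min
#> [1] 0.8642055
res$bias$value        # recovered the 1.2 cm/s baseline: 1.196934
```

Reading: the phantom's true net flow is 0.864 mL/min toward the head
(retrograde at the aqueduct); from one noisy realization the pipeline
recovers 0.812 mL/min and the correct direction, after removing the
1.2 cm/s baseline bias to within the noise. The per-frame flow curve is in
`res$curve`; `flag_low_snr()` reports whether the signal amplitude clears
the reference-noise floor.

File-based workflows use `read_phase_series()` / `read_roi_mask()` /
`read_acquisition_meta()` (NIfTI + YAML) and `write_metrics_table()`
(full-precision CSV); `inst/cli/csfflow` wraps the same functions as
`simulate` / `quantify` / `cohort` subcommands.

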