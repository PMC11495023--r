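---
title: "Quantifying cardiac-cycle-linked CSF flow from phase-contrast MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cardiac-cycle-linked CSF flow from phase-contrast MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfflow)
```

## The measurement problem

Cerebrospinal fluid (CSF) pulsates with every heartbeat through the Sylvian
aqueduct — the narrow channel between the third and fourth ventricles — and
across the cranio-cervical junction (CCJ). Cardiac-gated phase-contrast MRI
(PC-MRI) encodes the through-plane fluid velocity of each pixel in the image
phase, one 2-D frame per cardiac phase, averaged over many heartbeats. From
such a series, a region of interest (ROI) drawn inside the lumen, and a
second ROI in nearby static brain tissue, this package computes the
volumetric flow curve over one cardiac cycle and the derived clinical
metrics: stroke volume, antegrade and retrograde volumes, net flow per
cycle, per minute and per day, and a flow-direction label.

The quantity of interest is small. A net aqueduct flow of a few microlitres
per cycle — against pulsatile excursions one to two orders of magnitude
larger — decides whether net transport is antegrade (3rd to 4th ventricle)
or retrograde. Getting it right depends on three corrections applied in a
fixed order, each of which this vignette describes.

## The processing model

### 1. Velocity conversion

Stored pixel values are linear in velocity. With velocity-encoding limit
`VENC` (cm/s) and a stored-value scale `raw_scale` mapping to `+VENC`,

v = raw × VENC / raw_scale.

`to_velocity()` applies this map to the pixels of one ROI, producing an
`n_frames × n_pixels` matrix of velocities in cm/s. The package convention
is that positive velocity means flow toward the head (caudocranial); with
that one rule, positive net flow is retrograde at the aqueduct and upward
at the CCJ.

### 2. Aliasing correction

True velocities beyond ±VENC wrap by multiples of 2·VENC. The package
corrects aliasing by *temporal unwrapping* per pixel (`correct_aliasing()`):

* the anchor frame is the cardiac phase with the smallest ROI-mean absolute
  velocity — flow near its zero crossing is the least likely to be wrapped,
  and a wrapped frame cannot mimic a small mean-absolute-velocity frame
  unless the true velocity is a near-multiple of 2·VENC everywhere;
* walking the periodic series in both directions from the anchor, each
  inter-frame jump larger than VENC in magnitude is removed by shifting the
  farther sample by the nearest multiple of 2·VENC.

The corrected series has all consecutive jumps ≤ VENC, and the operation is
idempotent. It is exact — the inverse of the scanner's wrap — whenever every
*true* inter-frame jump is below VENC and peak velocities stay below
2·VENC. A series violating that condition is genuinely ambiguous: no
temporal filter can detect it, and the package documents rather than
guesses. Spatial unwrapping is deliberately not attempted; at a 26-pixel
lumen there is too little spatial support for it.

### 3. Reference-ROI bias correction

Eddy currents leave a static phase offset that appears as a spurious
constant velocity shared by the lumen and the surrounding tissue. The
reference ROI serves two purposes: its mean velocity estimates that bias,
which `subtract_bias()` removes from the CSF velocities, and its spread
(`noise_spread`, the SD of reference velocities about their frame means)
quantifies the noise floor.

The default bias mode is **global** — a single scalar, the mean over all
reference pixels and frames — because the eddy-current offset is static
over the cycle. A `per_frame` mode (subtracting each frame's reference
mean) is available by configuration for acquisitions with frame-dependent
baseline drift; it removes any common-mode signal per frame, so it also
removes real frame-synchronous artefacts and noise at the cost of slightly
higher variance.

Order matters: wrap arithmetic is only valid on the ±VENC scale, so the
chain is always *VENC scaling → aliasing correction → bias subtraction*.
Subtracting a bias that is not a multiple of 2·VENC before unwrapping would
corrupt the wrap lattice.

### 4. Flow integration

With pixel area `dx·dy` (cm²), the volumetric flow rate at frame time *t* is

Q(t) = (Σᵢ vᵢ(t)) × dx × dy  (mL/s, since 1 mL = 1 cm³),

and the signed net volume over one cycle is the discrete trapezoidal
integral

SV = (dt/2) Σᵢ (Q(tᵢ₊₁) + Q(tᵢ)),  dt = T / n_frames,

closed **periodically**: Q(t_{n+1}) ≡ Q(t₁). Periodic closure is the
physically meaningful choice for a gated cycle — the last frame is followed
by the first — and it makes the quadrature exact for any constant-plus-
sinusoid sampled uniformly over the period and second-order accurate
(O(n⁻²)) for other smooth waveforms. For uniform sampling it reduces to
`dt × Σ Q`, which is why antegrade plus retrograde volumes reproduce the
net integral *exactly*: the directional split clips each frame sample into
its positive part `max(Q, 0)` and negative part `min(Q, 0)` — which sum to
Q pointwise — and integrates each with the same rule. Clipping per frame
(rather than splitting the piecewise-linear interpolant at its zero
crossings) was a deliberate choice; the difference between the two
conventions is O(dt²), the same order as the quadrature error itself.

Note on terminology: the quantity called *stroke volume* here is the signed
net cycle integral (identical to net volume per cycle under periodic
closure). The conventional bidirectional aqueduct stroke volume — the mean
of |antegrade| and |retrograde| volumes — is exported separately as
`aux_conventional_stroke_volume` to avoid ambiguity.

### 5. Derived metrics and direction

Net flow per minute is `net_per_cycle × HR`; per day,
`net_per_min × 1440 / 1000` litres. The heart rate defaults to
`60 / cycle_duration` and, when supplied independently, must agree with
the cycle duration to a relative 10⁻⁶. Direction labels follow the sign
convention above: at the aqueduct, negative net flow is antegrade and
positive retrograde; at the CCJ, positive is upward and negative downward.
Net volumes smaller than `zero_tol` (default 10⁻¹² mL — far below any
measurable flow, so only exact zeros are labelled) classify as `"zero"`.

A worked example:

```{r example}
truth <- flow_ground_truth(profile = "parabolic",
                           mean_velocity_offset = 0.3,   # cm/s, toward head
                           pulsatile_amplitude = 3,      # cm/s
                           baseline_offset = 1.2,        # shared eddy bias
                           noise_sd = 0.5)               # cm/s
sim <- simulate_acquisition(truth, seed = 42)
res <- quantify_flow(sim$series, sim$target, sim$reference)
res$metrics
c(recovered = res$metrics$net_per_min,
  truth = sim$truth$true_net_mL_per_min)
```

## The synthetic phantom

No public reference acquisitions exist for this kind of measurement, so the
package ships a simulator (`simulate_acquisition()`) that produces gated
phase series with *exact* ground truth. It emulates:

* a circular lumen (default 26 pixels, the typical aqueduct ROI size) with
  a plug or parabolic (Poiseuille) spatial profile;
* a pulsatile-plus-offset waveform, optionally with extra harmonics:
  `v(p, t) = profile(p) × (offset + Σₖ aₖ sin(2πkt/T + φₖ))`;
* a static baseline offset added to *every* pixel, as eddy currents do;
* additive Gaussian velocity noise;
* optional wrapping into (−VENC, VENC], the scanner's aliasing operator.

Default acquisition parameters mirror a typical aqueduct protocol: 30
cardiac phases, VENC 10 cm/s, 0.06 cm isotropic pixels, heart rate 70 bpm.
The default noise level of 0.7 cm/s was set by closed-form propagation —
`sd(net/cycle) = dt · dx · dy · σ · √(n_frames · n_pixels)` ≈ 0.0029·σ mL —
so that repeat-measurement SDs land near 0.002 mL/cycle, the scale reported
for healthy-subject repeat scans at the aqueduct.

Two details keep recovery tests exact rather than approximate. The
continuum spatial mean of a parabolic profile is half the centre velocity,
but a 26-pixel mask measures that factor imperfectly; the simulator
therefore stores the *pixel-measured* factor `Σ profile(p) / n_pixels` in
its ground truth, so noise-free recovery is exact at any resolution, while
the continuum value 1/2 is recovered to within ~1% on a 200×200-pixel
lumen. And the noise model is Gaussian on velocity, not Rician on the
complex MR signal — a documented simplification that is accurate at
moderate-to-high SNR and keeps ground truth closed-form.

What the phantom does **not** model: respiratory modulation (which in vivo
dominates CSF flow and is outside cardiac-gated scope), bulk brain motion,
partial-volume effects at the lumen wall, and spatially varying coil bias.
Passing tests therefore demonstrate correctness of the *post-processing*
under the stated acquisition model, not robustness to every in-vivo
confounder.

## Noise screening

A target acquisition is flagged (never silently rejected) when the cycle
amplitude of its mean-velocity curve falls below
`k × noise_spread / √n_pixels`, with `k = 3` by default. In-vivo studies
exclude some acquisitions for noise, severe aliasing or an unidentifiable
lumen without a published rule; this threshold is this package's own
screening criterion and is configurable (`noise_flag_k`). NaN pixels are a
hard error — silent interpolation would bias the flux sums.

## Numerical and design choices

* **Periodic trapezoid**, not open-ended: the classical trapezoid formula
  references Q(t_{n+1}); defining it as Q(t₁) is the only choice consistent
  with gating and makes conservation exact (see above).
* **Frame times at bin midpoints** `(f − ½)·dt`: uniform spacing within
  [0, T); for periodic uniform sampling the integrals are unaffected by the
  phase of the grid.
* **1-based (row, col) indexing**, row 1 at the image top, shared by frames
  and masks — the natural R convention.
* **Full-precision CSV**: metric tables are written with the shortest
  round-trip decimal representation (`%.17g`) plus separate rounded display
  columns (3 decimals mL/cycle, 2 decimals mL/min), so downstream
  statistics never inherit display rounding.
* **Percent formatting** rounds half away from zero to one decimal, the
  clinical-table convention (15/24 → "62.5").
* **Descriptive cohort statistics only**: direction counts and proportions,
  mean ± SD (n−1) or median with range, and Pearson correlation of net flow
  against a covariate with listwise deletion. Inferential testing (ANOVA,
  chi-square, t-tests) is routine statistics available elsewhere in R and
  is out of scope here.

## Validation strategy and problem sizes

The test suite validates each stage against independent oracles: closed-form
integrals for the quadrature, a brute-force Riemann refinement of the
piecewise-linear periodic interpolant for random curves, the analytic
Poiseuille mean for the spatial profile, and simulator round trips for
aliasing and bias correction. End-to-end checks use 200 seeded noisy
simulations at the default fixture scale (26-pixel lumen, 30 frames, noise
0.5 cm/s) for parameter recovery, 1,000 random curves for conservation, and
five-repeat sets for the reproducibility design — sizes chosen to give
stable sampling statistics while keeping the whole suite in seconds.

## Known limitations

* Temporal unwrapping cannot detect aliasing when true inter-frame jumps
  exceed VENC; such acquisitions need a higher VENC or more frames.
* The bias model is a spatially uniform offset; polynomial background-phase
  surfaces are not fitted.
* Net flow here is *cardiac-cycle-linked* transport, not total CSF
  production: respiratory-driven flow, which cardiac gating averages away,
  is explicitly out of scope.
* Automatic lumen segmentation is not provided; masks are inputs.
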