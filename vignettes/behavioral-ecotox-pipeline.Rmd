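---
title: "Chip-based behavioral ecotoxicology with daphniachip: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chip-based behavioral ecotoxicology with daphniachip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(daphniachip)
```

## The assay this package models

*Daphnia magna* neonates (roughly 0.6 mm long, less than 24 h old) are a
standard sentinel organism for freshwater toxicity testing. Beyond the
classical acute endpoint — the fraction of animals immobilized after 24 or
48 h, scored as no reaction within 10 s — their locomotion is itself a
sensitive, fast-responding endpoint. Neonates swim in a characteristic
*hop-and-rest* cycle: brief antenna-powered bursts alternating with passive
rests during which they sink under gravity. Toxicants perturb this cycle
well below lethal concentrations, either depressing activity
(hypolocomotion; heavy metals, caffeine) or transiently exciting it
(hyperactivity; narcotic solvents such as ethanol or DMSO at low doses).

`daphniachip` implements the full analysis chain for such assays as run on
perfused millifluidic chamber arrays: vertically mounted 13 × 8 × 2 mm
chambers holding five free-swimming neonates each, back-illuminated and
filmed (30 s clips at 30 fps on the reference instrument), grouped in
clusters of three replicate chambers so that an eight-point dose-response
fits on one 24-chamber array. Because no public raw videos exist for this
assay format, the package also contains a first-class simulator that
generates ground-truthed synthetic data with the statistical structure the
pipeline assumes; every quantitative claim the package makes is exercised
as a parameter-recovery experiment against that generator.

## The locomotion model

`sample_trajectory()` draws hop-and-rest motion as an alternating-renewal
process:

* **Rests** are exponential. The mean rest is `1/hop_rate_hz -
  hop_duration_s`, so that hops are *initiated* at `hop_rate_hz` on
  average. This detail matters: it makes the expected actively swum
  distance per unit time exactly `hop_rate_hz * E[hop length]`
  (`expected_distance_rate()`), the closed form every recovery test uses.
  Had rests alone had mean `1/hop_rate_hz`, the realized hop rate would be
  biased low by the factor `1 + hop_rate * hop_duration` and no clean
  expectation would exist.
* **Hops** displace the animal by a `N(hop_length_mm_mean,
  hop_length_mm_sd^2)` length truncated at zero, spread uniformly over
  `hop_duration_s`. The direction is uniform in angle except that the
  vertical component points upward (against gravity) with probability
  `upward_bias`.
* **Sinking.** During rests the animal sediments at `sink_speed_mm_s`,
  clamped at the chamber floor. Hop displacements reflect specularly at the
  walls (the wall interaction is not documented for the real assay; specular
  reflection is the simplest choice that conserves path length).
* **Immobilized animals** are placed motionless inside the bottom 10% band
  of the chamber: an animal scored immobile has, by the time a clip is
  taken, sedimented to the floor. This is what makes the non-motile count
  recoverable from video alone.

The kinematic magnitudes are not published for this assay, so the defaults
— 1 hop/s, 1.5 ± 0.3 mm hops of 0.2 s, 0.5 mm/s sinking, upward bias 0.7 —
were chosen once to produce visually plausible hop-and-rest traces at
30 fps whose vertical drift roughly balances (mean upward hop flux ≈ mean
sink), and are not revisited. They are stand-ins for the study population,
not estimates of it; all are configurable.

Dose acts through `toxicant_effect()`: an `activity_curve(concentration,
time_h)` multiplies the hop rate (1 = no effect, 0.4 = strong
hypoactivity, 1.25 = hyperactivity, 0 = cessation) after an optional onset
lag, while immobilization is drawn per animal from the two-parameter Hill
model `F(c) = c^h / (EC50^h + c^h)`, which is exactly 0.5 at the EC50.

## Rendering and detection

`render_clip()` draws each animal as a dark ellipse (major axis = body
length, aspect 0.6, oriented along motion) on a light background with a
dark chamber border, with a Gaussian-profile edge of width `blur_px` and
additive Gaussian pixel noise. The default image scale maps the 13 mm
chamber height to 512 pixel rows — a desk-scale stand-in for the
instrument's 2048² sensor; the physics travels entirely through
`mm_per_px`.

Detection (`detect_clip()`) follows the classical pipeline: the static
background is the per-pixel temporal median of the stack (animals occupy
any pixel in a minority of frames), foreground pixels are those falling
more than `threshold_offset` below it, and 8-connected components within
0.25–4 × the expected animal area become detections with
intensity-weighted sub-pixel centroids. The threshold default is 5 × the
robust (MAD) noise SD of background-subtracted pixels — a parameter-free
choice, since the reference instrument's threshold is not published. The
area gate tolerates touching pairs and partial occlusion while rejecting
specks.

## Tracking

`link_tracks()` performs per-frame optimal one-to-one assignment between
live tracks and detections (Hungarian algorithm on squared distances),
with assignments beyond `gate_mm` × (1 + gap length) forbidden. Dropouts
up to `max_gap_frames` (default 3) are bridged by linear interpolation and
flagged; longer ones close the track. No motion model is used: constant
position is the right predictor for motion that is stationary most of the
time and ballistic for a few frames. The gate default, 4.5 mm, is three
mean hop lengths — the largest displacement a frame interval can plausibly
contain.

Identity swaps at close encounters are tolerated by design: all endpoints
are population averages per chamber, which swaps do not bias. They are
still measured (`evaluate_tracking()`), and the suite verifies the
expected density effect — markedly more swaps at 10 animals per chamber
than at 2, which is why the assay standardizes on 5.

## Endpoints and normalization

`track_metrics()` reports total distance, mean speed, and mean absolute
acceleration per track (acceleration is carried for completeness but given
no classification weight). Distance sums frame-to-frame displacements with
steps below `jitter_floor_mm` zeroed. The floor removes two non-locomotor
contributions at once: sub-pixel centroid jitter, and the passive
sedimentation drift during rests — gravity, not swimming. Its default,
0.08 mm per frame step, sits above the largest sedimentation step the
supported frame rates produce (0.5 mm/s → 0.05 mm at 10 fps, 0.017 mm at
30 fps) and far below any hop step (0.25 mm at 30 fps and up), so measured
distance estimates *active* locomotion and matches the generator's closed
form; the suite demands agreement within 5%.

A chamber summary averages per animal (dividing the summed track distance
by the known animal count, which is robust to track fragmentation),
reports the active fraction (clip distance > 2 body lengths — the
published assays name this endpoint but never define it; this is our
operationalization), and counts non-motile animals: tracks that stay
within `eps_mm` over every sliding 10 s window *and* sit in the bottom 10%
band. The 10 s window is the imaging analogue of the standard prodding
criterion; requiring sedimentation prevents a quietly drifting mid-water
animal from being scored dead.

Treated chambers are normalized to concurrent controls as `100 × (treated
− control) / control` from replicate chamber means (replicate chambers,
not pooled animals, are the statistical unit — matching the clusters-of-3
layout), with Student t-tests on the replicate values and a QC warning
when control replicates spread by ≥ 5%. Syndromes follow the published
thresholds: hyperactivity = +20% with p < 0.05 within 1–8 h of exposure;
cessation = −80% at the first post-exposure timepoint (no significance
requirement — the collapse itself is the signal); hypoactivity = −20% with
p < 0.05, a threshold chosen symmetric to the hyperactivity definition
since the assays report hypoactivity only via significance. Cessation
takes precedence over hypoactivity.

## Dose-response fitting

`fit_hill()` maximizes the binomial likelihood of immobile counts under
the two-parameter Hill curve, optimized on `(log EC50, log h)` — where the
curve is simply a logistic in log concentration — from three deterministic
starts. Binomial MLE respects the n = 15-per-concentration counts rather
than treating percentages as homoscedastic; a least-squares mode is kept
for comparison with conventional curve-fitting software. `ecx()` gives the
closed-form `ECx = EC50 (x/(100−x))^{1/h}`; `abbott_correct()` implements
the classical control-mortality rescaling, off by default (whether the
original analyses corrected is not stated, and control mortality above 5%
already fails assay QC); `bootstrap_ci()` resamples replicate rows within
concentration for a percentile interval. `behavioural_stats()` applies
one-way ANOVA per timepoint plus per-concentration Student t-tests against
control with raw p-values (Holm adjustment available but off by default,
matching the per-comparison convention of the source assays).

## Medium exchange as tanks in series

The three chambers of a cluster share one inlet, so a step change of
toxicant reaches them in sequence. `washout_profile()` idealizes each
chamber as a well-mixed compartment: `dC_i/dt = (Q/V_i)(C_{i−1} − C_i)`
with `C_0 = 1`. For equal volumes the k-th chamber follows the Erlang
breakthrough `C_k(t) = 1 − e^{−t/τ} Σ_{j<k} (t/τ)^j/j!` with `τ = V/Q`;
the numerical ODE path must agree with this closed form to 10⁻⁶, and does.
"Complete exchange" is operationalized at 95% — the published
characterization does not define its cutoff, and 95% reproduces the
observed timescale. At the defaults (208 µL per chamber, 5 mL/h per
cluster) `τ = 2.496` min and the 95% exchange times are 7.5, 11.8 and
15.7 min — strictly staggered along the series, with the third chamber
close to the experimentally observed ~15 min. Two caveats are deliberate:
connecting-channel volumes are neglected (in-chamber velocities are low,
so the CSTR idealization dominates the timescale), and the chip's stated
total inner volume (826 µL) is inconsistent with 24 × 208 µL chambers, so
the flow is taken per cluster; the model is an approximation and is
documented as such.

```{r washout}
cs <- compartment_series()
round(vapply(1:3, function(i) exchange_time(cs, i), 1), 2)
```

## What the synthetic tests do and do not show

The simulator reproduces the *statistical* structure of the assay:
renewal-process locomotion with dose-scaled activity, Hill immobilization,
dark-blob imaging with realistic noise, and replicate chamber layouts. It
deliberately omits: animal-animal interaction and collision avoidance,
fluid drag from the perfusion, 3-D motion (depth is carried but never
rendered — the reference analysis is 2-D), body-shape and orientation
endpoints, and feeding. Overlapping renders are allowed and serve as a
tracker stress case. Passing the suite therefore demonstrates that the
*pipeline* is correct and unbiased under the model's assumptions — e.g.
that a generative 0.4 activity multiplier is read out as a ~60% distance
decrease through detection, tracking and normalization — not that the
model captures every property of real chamber video.

Problem sizes were likewise chosen once at desk scale: recovery
experiments use 512-row frames, 15 s clips at 10 fps, 5 animals, 50 paired
seeds (behavior) and 7 concentrations × 15 animals × 200 seeds
(immobilization); property tests use 900-frame clips at reduced
resolution. These sizes give Monte-Carlo standard errors comfortably
inside the tolerances asserted.

## Numerical choices and degenerate inputs

* Assignment ties break to the lowest track id, then lowest detection x;
  detection records are sorted by centroid, so linking is independent of
  detection order within a frame.
* `hop_rate_hz = 0` yields a pure sinker; `sink_speed_mm_s = 0` a pure
  hopper; both together a fixed point. `apply_dose()` at concentration 0
  is an exact identity; a dosed hop rate that would leave no rest period
  shortens the burst instead of breaking the renewal structure.
* Hill fitting refuses fewer than 4 distinct positive concentrations and
  all-or-nothing responses (no partial response — the advice is to widen
  the concentration range). Convergence is reported honestly from the
  optimizer, and bootstrap intervals are flagged unreliable above 20%
  resample failures.
* `estimate_background()` requires ≥ 5 frames and subsamples long clips
  (51 evenly spaced frames); the median is insensitive to this.
* All stochastic entry points take explicit integer seeds; derived
  sub-seeds stay below 2³¹. Identical seeds give bit-identical
  trajectories, draws, pixels, and downstream tables.

## Known limitations

Endpoint recovery is validated against the package's own generative model,
the standard situation when raw assay data are unavailable; applying the
pipeline to real chamber video will require recalibrating `mm_per_px`,
the detection threshold, and the jitter floor to the instrument. The
tracker has no appearance model, so prolonged occlusions at high density
fragment tracks (population averages remain unbiased, and the per-animal
divisor keeps fragmented chambers comparable). The washout model predicts
bulk exchange, not spatial concentration gradients within a chamber.
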