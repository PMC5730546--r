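# daphniachip

Behavioral ecotoxicology pipeline for *Daphnia magna* neonates kept in
perfused millifluidic chamber arrays.

Acute *Daphnia* toxicity tests score immobilization after 24–48 h; the
animals' swimming behavior responds to the same toxicants within hours at
far lower concentrations. Chip-based assays film neonates (~0.6 mm) in
vertically mounted 13 × 8 × 2 mm chambers — five animals per chamber,
clusters of three replicate chambers, 24 chambers per array — and read out
locomotor endpoints from the videos. This package implements the complete
analysis chain for that assay format, plus the synthetic test bed needed to
validate it when no public raw videos exist:

* **Simulator** — hop-and-rest locomotion as an alternating-renewal
  process (exponential rests with gravity-driven sinking, truncated-normal
  hop lengths, upward-biased headings), dose-dependent activity
  modulation, per-animal immobilization from the Hill model, and rendering
  of back-illuminated chamber video with ground truth.
* **Detection** — temporal-median background, threshold segmentation,
  area-gated connected components with sub-pixel centroids.
* **Tracking** — per-frame Hungarian assignment with gating, gap bridging
  by interpolation, and identity-error scoring against ground truth.
* **Endpoints** — per-animal distance/speed/acceleration with a jitter
  floor that excludes sedimentation drift, active fraction, non-motile
  count (10 s stillness + sedimentation), normalization to concurrent
  controls, and syndrome classification (hypoactivity, hyperactivity =
  +20% within 1–8 h, cessation = −80% immediately).
* **Dose-response** — binomial maximum-likelihood Hill fits,
  `ECx = EC50 (x/(100−x))^(1/h)`, Abbott correction, bootstrap confidence
  intervals, chip-vs-plate correlation, ANOVA + t-tests vs control.
* **Mass transfer** — tanks-in-series washout of a chamber cluster,
  `dC_i/dt = (Q/V_i)(C_{i−1} − C_i)`, with the closed-form Erlang
  breakthrough for equal volumes and 95%-exchange times.

The central dose-response model throughout is the two-parameter Hill
curve, `F(c) = c^h / (EC50^h + c^h)`.

## Worked example

Simulate a copper-like assay (immobilization EC50 0.15 mg/L, Hill slope 2,
dose-dependent hypoactivity) on a 5-concentration layout with three
replicate chambers, analyze it through the truth-bypass lane, and fit the
immobilization counts:

```r
library(daphniachip)

eff <- toxicant_effect(ec50 = 0.15, hill_slope = 2,
                       activity_curve = function(c, t) 1 / (1 + (c / 0.6)^1.5))
design <- assay_design(concentrations = c(0, 0.05, 0.15, 0.5, 1),
                       replicates = 3, animals_per_chamber = 5,
                       sampling_times_h = 1, duration_s = 15, fps = 10,
                       units = "mg/L")
ds <- generate_assay(design, eff, seed = 42)
res <- analyze_assay(ds, mode = "truth")
res$normalized[, c("concentration", "time_h", "pct_change", "p_value", "label")]
#>   concentration time_h pct_change  p_value        label
#> 1          0.05      1      -4.96 0.637719         none
#> 2          0.15      1     -72.11 0.002362 hypoactivity
#> 3          0.50      1     -86.19 0.001700    cessation
#> 4          1.00      1    -100.00 0.000408    cessation

fit <- fit_hill(res$immobilization)
fit
#> Hill fit (binomial): EC50 = 0.1661 mg/L, slope = 1.83
ecx(fit, 10)
#> [1] 0.0499
```

Reading the output: at 0.05 mg/L the distance change is within control
noise (`none`); at the EC50 about half the animals are immobilized and the
rest mildly slowed, a −72% significant change (`hypoactivity`); at 0.5 and
1 mg/L locomotion collapses by more than 80% at the first timepoint
(`cessation`). The Hill fit recovers the generative EC50 (0.166 vs 0.15
mg/L from 15 animals per concentration) and puts the EC10 at 0.05 mg/L.

The same analysis runs on rendered video (`generate_assay(..., render =
TRUE)` then `analyze_assay(ds, mode = "video")`), on datasets written to
disk (`simulate_dataset()` / `analyze_dataset()`), or from the shell via
the thin CLI in `inst/cli/daphniachip` (`simulate`, `analyze`,
`doseresponse`, `masstransfer`).

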