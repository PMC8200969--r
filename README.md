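# dermaflux

Quantification of facial skin condition from at-home half-face photographs,
plus the longitudinal analytics to study its day-to-day fluctuation.

Fixed-geometry capture devices (a smartphone attachment with an LED and
gray reference tips) let people photograph their own cheeks reproducibly,
three times a day — morning after wake-up, morning after face wash, evening
after face wash — over an 8-week design (4 baseline weeks, 4 treatment
weeks). dermaflux implements the image side and the statistics side of that
workflow for researchers in cosmetic dermatology and skin imaging:

* **Calibration** — per-channel linear gain against the gray tips
  (`measure_gray()`, `calibrate()`), with clipped-pixel accounting.
* **Pore area** — dark quasi-circular blob detection on an edge-enhanced
  binary image: difference-of-Gaussians `G(σ_ℓ)∗L − G(σ_s)∗L`, robust
  `median + k·1.4826·MAD` threshold, 8-connected components screened by
  area, circularity `4πA/P²` and contrast; `total_area_au =
  1000·ΣA/A_ROI` (`pore_area()`).
* **Roughness** — RMS of the relative shadow map `L/(G_σ∗L) − 1` inside a
  Fourier annulus `[0.02, 0.15)` cycles/px (`roughness_score()`).
* **Redness** — hemoglobin index `h = log10(R/G)`; score = `100·mean(h)`
  (brightness) + `100·RMS` of the `[0.005, 0.05)` cycles/px band of `h`
  (variation) (`redness_score()`).
* **Fluctuation analytics** — side-averaged session records, weekly
  subject-first averages, **delta fluctuation** (daily max − min over the
  three timepoints), paired Wilcoxon signed-rank baseline and treatment
  contrasts with Holm adjustment, Welch's *t* between cohorts
  (`weekly_average()`, `delta_fluctuation_table()`,
  `compare_timepoints_baseline()`, `treatment_effect()`,
  `compare_studies()`).
* **Synthetic generator** — seeded skin patches with exact ground truth
  (pore geometry, in-band texture/blotch RMS, gains) and longitudinal
  cohorts `v = μ + b_s + τ_t + δ_t·1[week ≥ 1] + ε`, in values mode or
  rendered-image mode (`generate_patch()`, `generate_cohort()`), so the
  whole pipeline is testable without any data download.

All metric values are arbitrary units (au); only relative and ordinal
behavior is claimed. See `vignettes/dermaflux-methods.Rmd` for the models,
parameter rationale, and validation design.

## Worked example

```r
library(dermaflux)

# a synthetic 256x256 capture: gray tip, 30 pores of radius 4 px at the
# cheek, capture gains emulating a warm LED
lay <- patch_layout(c(256L, 256L))
g <- generate_patch(patch_params(size = c(256L, 256L), tip_roi = lay$tip,
                                 pore_region = lay$cheek, n_pores = 30L,
                                 pore_radius_px = c(4, 0),
                                 gains = c(1.15, 1.0, 0.9), seed = 7))
cal <- calibrate(g$image, measure_gray(g$image, lay$tip))
pore_area(cal, lay$cheek)
#> <pore_result: 30 pores, total area 57.792 au over 24000 px>
roughness_score(cal, lay$eye_to_cheek)
#> <roughness_result: 3.251 au in band [0.020, 0.150) c/px>
redness_score(cal, lay$cheek)
#> <redness_result: 11.405 au (brightness 9.651 + variation 1.754)>
```

All 30 placed pores are recovered. The analytic pore area of the scene is
`1000·30·π·4²/24000 = 62.8` au; the detected 57.8 au reflects the
radius-dependent residual bias of the thresholded-DoG mask discussed in
the vignette (the detector is calibrated to be unbiased at radius 5 px).
The roughness score reads the generator's 3% RMS texture as ≈ 3.25 au
(3.0 from texture plus in-band blotch energy), and redness decomposes into
the base tone's `100·log10(R/G) ≈ 9.65` plus the 2%-RMS blotch field's
≈ 1.75.

```r
# a 47-subject simulated cohort: baseline timepoint pattern and treatment
rec <- generate_cohort(cohort_params(seed = 1), mode = "values")
compare_timepoints_baseline(rec, "pore_area")
#> $`morning_wake vs morning_wash`
#> <wilcoxon_signed_rank morning_wake vs morning_wash: stat 1128, p adj 7.427e-09 (n 47) *>
#> $`morning_wake vs evening_wash`
#> <wilcoxon_signed_rank morning_wake vs evening_wash: stat 1128, p adj 7.427e-09 (n 47) *>
#> $`morning_wash vs evening_wash`
#> <wilcoxon_signed_rank morning_wash vs evening_wash: stat 1, p adj 7.427e-09 (n 47) *>
treatment_effect(rec, "pore_area")$delta_fluctuation
#> <wilcoxon_signed_rank delta_fluctuation treatment vs baseline: stat 0, p 2.476e-09 (n 47) *>
```

Pore area is largest in the morning after wake-up in every baseline week
(the first two contrasts; `stat` at its maximum 1128 = all 47 paired
differences positive), and the simulated treatment significantly reduces
the within-day delta fluctuation (`stat 0` = all differences negative).

## Command line

```sh
DERMA=$(Rscript -e 'cat(system.file("cli", "dermaflux.R", package = "dermaflux"))')
Rscript $DERMA simulate-cohort --mode images --seed 1 --out cohort/
Rscript $DERMA analyze --images cohort/ --sidecar cohort/sidecar.csv --out results/
Rscript $DERMA report --records results/metrics.csv --metric pore_area --out report/
```

Commands: `analyze`, `pores`, `roughness`, `redness`, `report`,
`simulate-patch`, `simulate-cohort`; every command accepts `--config
cfg.yaml` (unknown keys are rejected; the resolved config is written next
to the outputs) and `--seed`. Exit codes: 0 clean, 1 hard error, 2
completed with skips.

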