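---
title: "dermaflux: models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dermaflux: models, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

dermaflux quantifies three facial-skin conditions from half-face photographs
taken with a fixed-geometry capture attachment — total pore area, fine
surface roughness, and cheek redness — and analyzes their day-to-day
fluctuation over an 8-week observational design (4 baseline weeks, 4
treatment weeks, three sessions per day: morning after wake-up, morning
after face wash, evening after face wash). This vignette explains the
models behind each score, the parameters that matter and why their defaults
are what they are, what the synthetic generator does and does not emulate,
and the numerical choices a maintainer should know about.

## Color calibration

Each frame carries neutral gray tips at a fixed position. Calibration is a
von-Kries-style per-channel linear gain: channel $c$ is multiplied by
$g_c = \rho / \bar{x}_c$, where $\bar{x}_c$ is the tip-ROI channel mean and
$\rho$ the tip's nominal reflectance (default 0.5, configurable). This is
the minimal model consistent with a single neutral reference: it cancels
any per-channel exposure or illuminant gain exactly, which is what the
calibration-invariance tests verify (post-calibration scores under random
gains in $[0.5,2]^3$ agree with the unit-gain reference to well under 2% on
clipping-free scenes). No offset term and no cross-channel matrix are
fitted — a single gray level cannot identify them. Pixels that clip at 1
after gain are counted and reported (`$n_clipped`), never silent: clipping
biases every downstream metric. A tip-ROI channel coefficient of variation
of 0.2 or more flags the reference as suspect (occluded or misplaced tip)
but still returns the measurement.

## Pore area

Pores are small dark quasi-circular blobs. The pipeline is:

1. Rec. 709 luminance of the calibrated cheek ROI.
2. Difference-of-Gaussians enhancement
   $\mathrm{DoG} = G_{\sigma_\ell} * L - G_{\sigma_s} * L$
   ($\sigma_s = 1.5$ px, $\sigma_\ell = 6$ px), positive where a pixel is
   darker than its surround, DC-free.
3. Robust binarization at $\mathrm{median} + k \cdot 1.4826\,\mathrm{MAD}$
   of the response.
4. 8-connected component screening: area in $[9, 2000]$ px, circularity
   $4\pi A / P^2 \ge 0.6$ (perimeter by Moore-neighbor contour tracing,
   diagonal steps counted $\sqrt2$; the ratio is capped at 1), luminance
   deficit at least 0.02, border-touching components discarded.
5. `total_area_au` $= 1000 \sum A_i / A_{\mathrm{ROI}}$ — ROI-size
   independent. The instrument's absolute au scale is unrecoverable, so
   only relative and ordinal behavior is claimed.

All defaults assume the generator's scale of roughly 10 px/mm.

**Why $k = 3.5$.** The binarization offset was calibrated, once, against
the generator's analytic ground truth: the thresholded-DoG mask carries a
roughly constant-width dilation, so its relative area bias depends on
radius (strongly positive for pores much smaller than $\sigma_\ell$,
negative beyond it). At $k = 3$ the mask of the reference pore (radius 5 px,
30% contrast, 3% RMS texture) is consistently ~7% too large and texture
false positives add a few percent more; at $k = 3.5$ the threshold crosses
the DoG edge profile of the reference pore at its true boundary, measured
recovery is unbiased within about ±1%, and texture false positives
disappear. The radius dependence of the residual bias is a known
limitation: at fixed $k$ the detector over-reads pores much smaller than
$\sigma_\ell$ and under-reads much larger ones, so absolute comparisons
across very different pore-size populations need a per-population
calibration.

## Roughness (shadow spectrum)

Fine topography casts small local shadows. The relative shadow map is
$s = L / (G_{\sigma_{\mathrm{illum}}} * L) - 1$ with
$\sigma_{\mathrm{illum}} = 30$ px: dividing by the large-scale local mean
cancels slow illumination and face-shape shading and makes the map
invariant to global brightness gain. The score is
$100 \times \mathrm{RMS}$ of the component of $s$ inside a radial
spatial-frequency annulus $[0.02, 0.15)$ cycles/px (about 0.2–1.5
cycles/mm): texture varies at sub-millimeter scales. RMS-in-band was chosen
over histogram or entropy summaries because it has exact analytic checks
(Parseval; quadrature additivity of independent fields), and the
measurement is made with a 2-D Hann taper, compensated by the window power
$\overline{w^2}$, because uncorrected border leakage otherwise dominates
small ROIs. A hard (ideal) annulus keeps the band interpretable.

## Redness

Hemoglobin absorbs green preferentially, so the erythema-style
optical-density contrast $h = \log_{10}(R/G)$ rises with blood content
(full Beer–Lambert unmixing of hemoglobin against melanin would need
absorption spectra and more bands than RGB provides). The score has two
parts computed on the cheek ROI: brightness $100\,\overline{h}$ and
variation $100 \times \mathrm{RMS}$ of the Fourier-annulus band-pass of
$h$ in $[0.005, 0.05)$ cycles/px — an order of magnitude below the
roughness band, because erythema blotches vary over mm–cm scales. The two
components are combined by unweighted sum (the original instrument's
weighting is unknown; weights are configurable). The spatially constant
part of $h$ lands entirely in the brightness component: the annulus
excludes DC, so a uniform shift $c$ moves brightness by exactly $100c$ and
variation by nothing. Redness deliberately depends on calibration — an
uncalibrated red cast shifts the score, and gray-tip calibration removes
it.

## Fluctuation analytics

All analytics run on the side-averaged record table (left/right half-face
values of one session averaged, since the study reports one value per
session). Delta fluctuation of a subject-day is the highest minus the
lowest of its three timepoint values; incomplete days are skipped and
reported, never imputed. Weekly averages are subject-first (mean over each
subject's available days, then unweighted mean over subjects) so unequal
day counts do not reweight subjects. Baseline timepoint contrasts use the
paired Wilcoxon signed-rank test on per-subject baseline means, Holm-
adjusted across the three pairs (the source protocol says only
"nonparametric, paired"; Holm is assumption-free and conservative, and can
be disabled). Treatment effects compare week 4 against week −4 per
timepoint (the figure captions' reference week; a pooled-baseline option
exists), plus a paired test of subject-mean delta fluctuation, treatment
vs baseline period. Between-study comparison is Welch's *t* on subject
baseline means. The signed-rank null is exact for ≤ 25 nonzero pairs
without ties and a normal approximation with continuity and tie correction
otherwise; both kernels are implemented in-package and match the stock R
implementations to 10⁻⁸ in the test suite. Analysis of (co-)variance is
out of scope: no covariate model is specified for it.

## Synthetic generator: what it emulates, what it does not

A patch composes base skin tone → multiplicative illumination gradient
(10% peak diagonal shading) → band-limited shading texture with exact
in-band RMS (default 3% — plausible fine-texture shading) → anti-aliased
dark pore disks (default 30% luminance drop; radii ~0.3–0.9 mm at
10 px/mm) → a band-limited hemoglobin blotch field applied
antisymmetrically to R and G (default 2% RMS in $h$ units) → painted gray
tip → per-channel capture gains → 8/16-bit quantization. Every stage is
seeded and the true parameters are returned for recovery tests.

The cohort simulator draws session values from
$v = \mu + b_s + \tau_t + \delta_t \mathbf{1}[\text{week} \ge 1] +
\varepsilon$ with subject effects $b_s$ and session noise $\varepsilon$.
The pore set ($\mu = 100$, $\tau = (+8, 0, +2)$,
$\delta = (-8, -3, -3)$, $\sigma_s = 10$, $\sigma_n = 4$ au) and the
redness timepoint ordering $\tau = (+1, 0, +6)$ are fixed by the design
contract; the roughness and redness sets are scaled analogues chosen so a
47-subject cohort reproduces the qualitative fluctuation patterns
(morning-wake largest for pore and roughness, evening largest for
redness). Sessions drop out independently with probability 0.05 — the
plain completer-cohort reading; the study's collected-image totals do not
factor into any simple subjects × days × sessions scheme, and no dropout
model is attempted.

In image mode each session value maps affinely and monotonically onto
patch parameters and a 256×256 patch is rendered (tip top-left, pore-free
eye-to-cheek region left, pored cheek region right). Two mapping choices
are deliberate and worth knowing: pore density is kept sparse (~6% cheek
coverage at 100 au) because the median+MAD threshold treats pores as
response outliers and turns compressive at high coverage; and the cheek
region carries a fixed 3%-RMS texture while the eye-to-cheek region
carries the roughness-mapped amplitude (one continuous field,
region-scaled amplitude), because the binarization threshold scales with
cheek texture and would otherwise bleed the roughness signal into the
detected pore area. With these choices the closed loop
(simulate → analyze) recovers all three generating values with Spearman
ρ ≳ 0.92 and reproduces the fluctuation patterns end to end.

What a green test does **not** establish: patches are statistically
stationary fields, not faces — no pose or focus variation, no specular
highlights, no hair/occlusions, no melanin structure, no sebum gloss, and
the au scales are the package's own, not the original instrument's.
Agreement with the generator validates internal consistency and relative
behavior, not clinical equivalence.

## Numerical choices and degenerate inputs

* Gaussian smoothing is separable with whole-sample reflective boundaries,
  truncated at 3σ and renormalized (a constant raster is reproduced
  exactly); it is applied as banded operator matrices so the work stays in
  BLAS.
* `binarize` returns an empty mask on a zero-variance response; rasters
  smaller than $6\sigma_\ell$ per side are size errors.
* Component perimeters come from Moore-neighbor tracing with a
  deterministic (pixel, backtrack)-state termination; 1–2 px components
  have degenerate contours and their capped circularity is 1.
* Candidate ordering is area-descending with (row, col) centroid
  tie-breaks, so results are stable across platforms.
* Luminance and channel ratios are floored at $10^{-4}$ before division
  and logs.
* Bands are validated to $0 < \mathrm{low} < \mathrm{high} \le 0.5$
  cycles/px.
* Image files: PNM (8/16-bit) is read and written natively; PNG/JPEG are
  read when the optional `png`/`jpeg` packages are present. Metadata
  travels in a sidecar CSV, not EXIF — deterministic and
  format-independent.
* The cheek ROI's placement within a real half-face frame is not specified
  by the capture protocol; ROIs are always user- (or generator-) supplied.

## Known limitations

* Radius-dependent residual bias of the thresholded-DoG area estimator
  (see above).
* Single-level gray calibration cannot correct nonlinearity (multi-level
  tips would allow a linearization, and "tips" plural suggests the
  hardware may carry them).
* The roughness and blotch bands overlap in $[0.02, 0.05)$ cycles/px; on
  real skin, strong erythema texture can contribute to the roughness
  score.
* Weekly tests are marginal per timepoint; no longitudinal mixed-effects
  model is fitted.
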