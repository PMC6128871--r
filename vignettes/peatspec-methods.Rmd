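---
title: "Quantifying carbohydrates and aromatics in peat by ATR-FTIR: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying carbohydrates and aromatics in peat by ATR-FTIR: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peatspec)
```

## The problem

Mid-infrared (ATR-FTIR) spectra of peat and plant material are fast and
cheap to acquire but not inherently quantitative: overall absorbance varies
with sample matrix and contact against the ATR crystal, band positions
drift with sample chemistry, and bands ride on sloping baselines.
Classical practice reduces spectra to humification indices — ratios of an
aromatic or aliphatic band to the carbohydrate band — which cannot say
*which* component changed. peatspec implements a peak-height workflow that
produces absolute estimates instead: weight-percent carbohydrates
(acid-hydrolysable polysaccharides, from the ~1030 cm^-1 band) and
weight-percent aromatics (Klason lignin plus other acid-insoluble
unsaturated material, from the ~1510 and ~1630 cm^-1 bands), with a stated
per-sample uncertainty.

The chain has four links, each implemented and tested separately:

1. **Adaptive peak endpoints.** Band limits shift between samples, so for
   each band the two endpoints are located per sample inside configured
   search windows (`find_endpoint()`). The primary rule takes the local
   minima of the full spectrum inside the window (plateaus admitted: a
   point no higher than both neighbours) and picks the lowest; when the
   spectrum is monotone through the window, the fallback picks the maximum
   of the discrete second derivative — the point of strongest upward
   curvature where the band shoulder flattens out.
2. **Chord baseline correction.** The straight line between the two
   endpoint absorbances is subtracted (`baseline_correct()`). Any affine
   component of the local background is absorbed exactly.
3. **Area normalization.** The corrected peak height is divided by the
   total trapezoidal integral of the spectrum (`integrate_spectrum()`),
   removing matrix- and instrument-induced differences in overall
   absorbance. The resulting *normalized corrected peak height* (units cm)
   is invariant under rescaling of the spectrum, and is the quantity all
   downstream statistics consume.
4. **Wet-chemistry calibration.** Normalized heights of a 58-material
   standard set (woods, leaves and grasses, needles, and paper products)
   are regressed on measured % cellulose + hemicellulose and % Klason
   lignin (`fit_calibration()`), and the fitted lines convert heights to
   composition for unknown samples (`predict_composition()`).

## Decisions the data model forces

**Tie-breaking and determinism.** Neither the local-minimum rule nor the
corrected-height argmax has a unique answer on plateaus. Both break ties
toward the lowest wavenumber. This is arbitrary but fixed: identical inputs
give identical outputs everywhere, which the pipeline tests assert at the
byte level.

**Second derivative without smoothing.** The fallback uses central finite
differences on the raw grid (non-uniform grids use divided differences).
Pre-smoothing is available (`smooth_width`, odd moving-average width) but
off by default: raw differences keep the operation parameter-free, and the
fixtures the package validates against are noise-free precisely where the
fallback fires.

**Ascending canonical grid.** Instrument exports conventionally run from
4000 down to 650 cm^-1; spectra are canonicalized to ascending order once
at load, so integrals and derivatives never need sign conventions.

**Negative absorbance and non-positive areas.** Negative values are
permitted (baseline artifacts); they integrate with sign. A spectrum whose
total area is not positive cannot be normalized — the measurement refuses
rather than silently producing nonsense, and PCA excludes such samples
with a warning.

**Endpoint search windows.** The packaged defaults
(`inst/extdata/peaks.yml`) bracket each band with windows of 40–120 cm^-1
on each side, placed in the natural valleys between the five organic
bands. They are explicit defaults: for production use they should be
reconciled with the band table validated for the instrument and sample
set at hand. The ~1630 cm^-1 aromatic band is nominally quoted anywhere
between 1615 and 1630 cm^-1 in the literature; the nominal position is a
label only (the measured position adapts), and is configurable.

**Silicate screening.** Mineral-bearing sections produce a large band
overlapping the carbohydrate peak. The screen (`screen_silicate()`) flags
a spectrum when kaolinite diagnostics (3695 *and* 3620 cm^-1) or the
780 cm^-1 silicate band are present *and* the ~1030 cm^-1 peak is large.
Both thresholds are configured in normalized-height units; no published
numeric threshold exists, so the defaults classify the package's
constructed positive and negative fixtures correctly and the flag is
advisory — exclusion is always a recorded metadata decision, never an
automatic deletion.

## Calibration design

The carbohydrate calibration drops the old-magazine (OMG) standards, whose
clay coating adds a mineral band inside the carbohydrate window; the
aromatic calibration drops the office-paper (OFF) standards, a chemical
pulp with the lignin removed. Both exclusions leave n = 54.

Aromatics are predicted from the *sum* of the 1510 and 1630 cm^-1
normalized heights, treated as a single x-variable rather than two
covariates: the partition of aromatic absorbance between the two bands
varies widely between materials, so each band alone predicts Klason lignin
much worse than their sum. `compare_aromatic_predictors()` fits all three
candidates and reports the ranking; prediction always uses the summed-peak
model.

The attached uncertainty is the calibration's standard error of the
y-estimate, `see = sqrt(SSE / (n - 2))`, used as a constant per-sample
standard error. Estimates are deliberately *not* clipped to [0, 100] wt%:
clipping would bias cross-sample comparisons, so out-of-range estimates
surface with a warning instead. No weighting and no intercept suppression
are applied — the calibration is a plain simple regression, and the
reported p-value is the two-sided slope t-test (identical to the F-test
here).

## Downstream statistics

* **Surface summaries** average estimated composition over core sections
  whose depth is at most 50 cm, reporting mean ± sample SD (n − 1) per
  core. Section depth is the representative (midpoint) depth of the
  section — the conventional choice for interval-sampled cores.
* **Trend regressions** are unweighted OLS of per-core surface means on
  latitude or mean annual temperature, one point per core. Weighting by
  within-core SD was considered and rejected: the SDs describe
  within-core heterogeneity, not sampling error of the mean, and
  unweighted regression keeps the estimator identical to the calibration
  fit.
* **Plant–peat and latitude contrasts** use Student's pooled-variance
  two-tailed t test, not Welch: the pooled form is the one whose degrees
  of freedom (n_a + n_b − 2) match grouped contrasts of this design — for
  example 39 samples split 24/15 give t(37). Groups of one report
  "not determinable"; zero-variance degeneracies are handled explicitly
  (equal constant groups: t = 0, p = 1).
* **LOESS depth profiles** use degree-2 local polynomials with tricube
  weights, span 0.75, fitted exactly (`surface = "direct"`) and split into
  high- and low-latitude groups at 45°N — the midpoint between pole and
  equator, with the boundary counting as high so that a 45.4°N bog is
  high-latitude. The 95% band is a pointwise normal approximation from the
  local fit's standard error; plotting defaults elsewhere use a t
  quantile, a difference that is immaterial at these group sizes. Curves
  are evaluated on an even 100-point depth grid per group.
* **PCA of whole spectra** first interpolates to the common overlapping
  grid and rescales every spectrum so its integrated area is exactly 100,
  then runs `prcomp` on the column-centered, non-variance-scaled matrix —
  the ordination convention for spectral data. Component signs are fixed
  (largest-magnitude loading element positive) so results are
  reproducible.
* **External-variable vectors** regress each variable on the first two
  score axes; the arrow is the unit coefficient vector and significance
  comes from a seeded permutation test (default 999 permutations; the
  seed is mandatory). Depth, latitude and temperature are fitted on peat
  samples only — plants have no depth, and their collection latitudes do
  not correspond to the peat transect. Constant variables report r² = 0,
  p = 1 with a warning. The implementation is cross-checked in the test
  suite against an independent ordination package.

## What the synthetic data emulate — and what they do not

All tests run on generated data with known ground truth; nothing is
downloaded.

`generate_spectrum()` builds sums of Gaussian bands plus an affine
baseline and white noise on a 650–4000 cm^-1 grid at 2 cm^-1 spacing
(1676 points — the storage density of a nominal 4 cm^-1 instrument).
Gaussian shapes were chosen over Lorentzian/Voigt because they are the
simplest shape with an analytic area and fully exercise the endpoint,
baseline and normalization logic; no ATR radiative-transfer physics is
attempted.

`generate_calibration_set()` emulates a 58-standard calibration with
4 OMG and 4 OFF standards and a linear height–composition map
(20 000 wt% per cm for carbohydrates, 8 000 for aromatics — magnitudes
that put normalized heights at a few 10^-3 cm). Its defaults are fixed by
design to a calibration of realistic strength: compositions uniform on
20–82 wt% with a 9 wt% observation SD for carbohydrates (expected
R² ≈ 0.80) and uniform on 8–28 wt% with a 5 wt% SD for aromatics
(expected R² ≈ 0.57). These choices follow from the closed-form identity
R² = var(signal) / (var(signal) + σ²) and were not adjusted afterwards.
OMG standards receive a positive carbohydrate-height bias (the clay band)
and OFF standards a low lignin content with an aromatic-height bias, so
the exclusion rules do real work.

`generate_standard_spectra()` realizes a standards table as spectra whose
*measured* normalized corrected heights reproduce the stored heights: the
self-consistency between raw band heights and the total area they
themselves contribute is solved analytically per sample. Each spectrum
carries a per-sample random background — a broad O–H band, a variable
broad shoulder under the aromatic region (σ = 150 cm^-1, half-normal
height with SD 0.12 absorbance), an offset and a tilt. The shoulder is
the point of the exercise: it contaminates *raw* heights heavily but is
almost entirely removed by the endpoint chord, so refitting the
calibrations on non-baseline-corrected heights degrades the aromatic R²
substantially while leaving the carbohydrate R² essentially unchanged —
the situation that motivates baseline correction in the first place. The
small chord residual of the shoulder also attenuates the spectra-measured
aromatic calibration a little relative to its design value; that
attenuation is visible in the acceptance report and is expected.

`generate_transect()` emulates a pole-to-equator peatland transect: 14
cores at the latitudes of real northern-to-tropical study sites, sections
every 10 cm to 195 cm, carbohydrates rising with latitude
(+0.55 wt%/deg from 18 wt% at the equator) and declining with depth in
high-latitude cores (−0.15 wt%/cm), aromatics falling with latitude
(−0.45 wt%/deg from 48 wt%), between-sample noise of 5 wt%, and 39 plant
samples (noise 7 wt%) spread across the site latitudes — which yields the
24/15 high/low split and hence t(37) contrasts. Mean annual temperature
is the idealized gradient 28 − 0.42·latitude °C. Compositions are clamped
to [2, 95] wt%.

What the generators do **not** emulate: real band overlap and Fermi
resonances, detector nonlinearity, ATR penetration-depth effects, water
vapour lines, spatial autocorrelation down-core, and non-Gaussian
between-sample variability. Passing tests therefore demonstrate that the
algorithms are correct and the workflow recovers known parameters under
realistic noise — not that any particular field data set satisfies the
linearity assumptions.

## Numerical choices and problem sizes

Integration is the composite trapezoid on the native grid (exact for the
piecewise-linear fixtures). Endpoint matching requires grid coincidence to
a 1e-8 relative tolerance — no silent interpolation. Permutation p-values
use the add-one estimator (1 + exceedances)/(n_perm + 1). All generators
restore the caller's RNG state; every stochastic entry point takes a
mandatory seed.

The test suite sizes are deliberate: oracle comparisons (closed-form OLS,
pooled t, eigendecomposition PCA, tricube local WLS) run on ≤ 20-point
fixtures at 1e-8 tolerances; parameter-recovery properties use 500
calibration replicates (slope and intercept within 3 SE in ≥ 99%) and 200
spectra-free transects (±2 true-SE coverage ≥ 95%); the end-to-end
spectral pipeline runs three full transects of 319 spectra each. A single
±2-SE interval is itself a ~95% event, so single-shot end-to-end recovery
is asserted on two of three independent replicates rather than on one.

## Known limitations

* Calibration transfer: the linear maps are only as good as the standard
  set; transect aromatics (up to ~48 wt%) extrapolate beyond the 8–28 wt%
  calibration range, which is harmless for a truly linear response but
  untested chemistry in practice.
* The constant SEE understates uncertainty far from the calibration
  centroid; per-point prediction intervals are a documented extension.
* Endpoint adaptivity means exact affine invariance of corrected heights
  holds only when window minima are sharp; on noise-dominated windows a
  global ramp can move an endpoint by a grid step.
* The workbook reader handles wide CSV and XLSX layouts with a
  configurable metadata block; JCAMP-DX is not parsed.
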