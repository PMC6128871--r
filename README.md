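# peatspec

Quantitative ATR-FTIR chemometrics for peat and plant organic matter.

## What it does and for whom

Peat accumulates where plant litter decomposes slower than it is
deposited, and the balance between its two chemically decisive
constituents — labile **carbohydrates** (polysaccharides, the most
reactive solid-phase fraction) and decomposition-inhibiting **aromatics**
(lignin, tannins, humics, char) — controls how recalcitrant a peat is and
how it will respond to warming. peatspec is for biogeochemists and
peatland scientists who want absolute estimates of those two fractions
from routine ATR-FTIR spectra instead of relative humification indices,
plus the downstream statistics used to compare sites along climatic
gradients.

## The method

For a spectrum A(ν) on 650–4000 cm⁻¹, each target band (carb ~1030,
arom15 ~1510, arom16 ~1630, aliph28 ~2850, aliph29 ~2920 cm⁻¹) is
quantified per sample as:

1. **Endpoints** νₗ, νᵣ found adaptively in configured search windows:
   the lowest local minimum of A in the window (ties → lowest ν), falling
   back to the maximum of the discrete second derivative A″ when the
   spectrum is monotone through the window.
2. **Baseline correction** by the endpoint chord:
   A\*(ν) = A(ν) − [A(νₗ) + (A(νᵣ) − A(νₗ)) (ν − νₗ)/(νᵣ − νₗ)].
3. **Peak height** h = max A\*(ν) over (νₗ, νᵣ), at the adapted peak
   position.
4. **Area normalization** ĥ = h / ∫A(ν)dν (trapezoid over the full
   range), giving the *normalized corrected peak height* (cm), invariant
   to overall absorbance scaling.
5. **Calibration** against wet chemistry on a 58-material standard set:
   % cellulose + hemicellulose = a·ĥ_carb + b (OMG standards excluded,
   n = 54) and % Klason lignin = a·(ĥ_arom15 + ĥ_arom16) + b (OFF
   standards excluded, n = 54), by ordinary least squares; the standard
   error of the y-estimate √(SSE/(n−2)) is the per-sample uncertainty.

Downstream: surface-peat (≤50 cm) means ± SD per core, OLS trends
against latitude and mean annual temperature, pooled-variance t contrasts
of plant and peat chemistry, degree-2/span-0.75 LOESS depth profiles by
latitude group (split at 45°N), PCA of whole spectra rescaled to
integrated area 100, and permutation-tested external-variable vectors on
the score plane. Silicate-bearing samples (kaolinite 3695 + 3620 cm⁻¹ or
780 cm⁻¹ bands together with a large ~1030 cm⁻¹ peak) are flagged for
auditable exclusion.

A seeded synthetic-data module generates band-mixture spectra,
calibration sets and latitudinal transects with known ground truth, so
the entire workflow is testable end to end without any external data.

## Worked example

```r
library(peatspec)

standards <- generate_calibration_set(seed = 101)
transect  <- generate_transect(transect_params(seed = 102))

s <- transect$spectra[["core01_d005"]]
s
#> <ftir_spectrum> core01_d005: 1676 points, 650-4000 cm^-1 (acquired as absorbance)

m <- measure_all(s)
m[, c("peak_name", "peak_position", "corrected_height", "normalized_height")]
#>   peak_name peak_position corrected_height normalized_height
#> 1      carb          1030           0.9258          0.003058
#> 2    arom15          1508           0.2725          0.000900
#> 3    arom16          1630           0.3380          0.001117
#> 4   aliph28          2850           0.0457          0.000151
#> 5   aliph29          2924           0.0496          0.000164

calibrate_analyte(standards, "carbohydrates")
#> <calibration_model> carbohydrates ~ carb: slope 1.964e+04, intercept -4.52
#>   R^2 = 0.815, p = 1.13e-20, n = 54, SEE = 8.77 wt%

carb_model <- calibrate_analyte(standards, "carbohydrates")
predict_composition(carb_model, m$normalized_height[m$peak_name == "carb"])
#>   estimate       se
#> 1  55.5419 8.772412
```

The measured band heights adapt to each sample (the 1510 cm⁻¹ band was
found at 1508), the carbohydrate height of 0.003058 cm converts to an
estimated 55.5 ± 8.8 wt% carbohydrates — the generator's ground truth for
this sample is 55.7 wt% — and the calibration itself reports its fit
(R² = 0.815 on 54 standards) and uncertainty (SEE = 8.77 wt%).

Running the whole study at once:

```r
res <- run_full_pipeline(run_config(
  standards = standards, spectra = transect$spectra,
  records = transect$records, out_dir = "report", seed = 7, n_perm = 999))

res$regressions[1:2, c("response", "covariate", "slope", "r_squared", "p_value", "n")]
#>    response    covariate  slope r_squared  p_value  n
#> 1 mean_carb latitude_deg  0.476     0.902 2.06e-07 14
#> 2 mean_arom latitude_deg -0.411     0.866 1.38e-06 14

res$t_tests[, c("variable", "t", "df", "p_value")]
#>   variable      t df   p_value
#> 1 carb_est -4.728 37 3.260e-05
#> 2 arom_est  4.929 37 1.757e-05
```

Surface-peat carbohydrates rise with latitude (+0.48 wt% per degree) and
aromatics fall; low-latitude plants are significantly poorer in
carbohydrates (negative t for the low-minus-high contrast) and richer in
aromatics. `report/` receives one CSV per result table plus a JSON
manifest accounting for every sample as included or excluded with a
reason.

A thin command-line front end ships in `inst/cli/peatspec`
(`convert`, `measure`, `calibrate`, `predict`, `simulate`, `run`).

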