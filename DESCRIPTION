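Package: peatspec
Title: Quantitative ATR-FTIR Chemometrics for Peat and Plant Organic Matter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates carbohydrate and aromatic content of peat and plant
    organic matter from attenuated total reflectance Fourier transform
    infrared (ATR-FTIR) spectra. Implements per-sample adaptive peak-endpoint
    detection (local minima with a second-derivative fallback), endpoint-chord
    baseline correction, peak heights normalized to the total integrated
    spectral area, silicate interference screening, and linear calibration of
    the normalized heights against wet-chemistry reference values
    (cellulose + hemicellulose, Klason lignin). Includes the downstream
    statistical workflow for latitudinal peat transects: surface-peat
    summaries, latitudinal and temperature regressions, pooled t contrasts of
    plant and peat chemistry, LOESS depth profiles, principal components
    analysis of whole spectra with permutation-tested external-variable
    vectors, and humification indices. A seeded synthetic-data module
    generates band-mixture spectra, calibration standard sets and latitudinal
    transects with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    readxl,
    optparse
Config/testthat/edition: 3
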