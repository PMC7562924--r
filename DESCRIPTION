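Package: biodynr
Title: Biodynamic Doppler Spectroscopy Chemosensitivity Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for drug-response profiling of living tumor
    biopsies from Doppler fluctuation spectroscopy. Converts per-well
    fluctuation power spectra into baseline-referenced drug-response
    spectrograms with data-quality weighting and vehicle-control subtraction,
    extracts time-frequency biomarkers with Legendre filter masks and
    spectral-shape preconditions, orthogonalizes biomarkers by singular value
    decomposition with z-factor ranking, builds correlation-contrast
    similarity networks, and assigns resistant or sensitive chemosensitivity
    phenotypes with a four-classifier ensemble evaluated by leave-one-out
    cross-validation and Gaussian-mixture ROC analysis. Includes a seeded
    synthetic-cohort generator emulating phenotype-dependent spectral drug
    responses for fully reproducible end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    minpack.lm
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
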