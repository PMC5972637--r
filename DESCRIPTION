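Package: ncvw
Title: Nearest-Correlation Variable Weighting for Spectral Calibration Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Soft-sensor calibration modelling for high-dimensional spectral
    data (e.g. near-infrared spectra) built around the nearest-correlation
    (NC) family of methods: NC similarity search, NC spectral clustering of
    wavelengths, NC-based variable-group selection and group lasso, and
    NC-based input variable weighting (NCVW), in which each wavelength is
    weighted by its correlation similarity to the response before partial
    least squares (PLS) regression. Includes a NIPALS PLS implementation with
    cross-validated latent-variable selection, PLS-Beta and VIP importance
    measures, lasso and stepwise comparators, Savitzky-Golay derivative
    preprocessing, a synthetic NIR-like spectra generator with known
    ground-truth response structure, and a method-comparison harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    signal,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
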