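Package: authentispec
Title: Spectral Fingerprinting Pipelines for Food Authenticity Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric pipelines for classifying vibrational (ATR mid-infrared,
    near-infrared) and 1H-NMR spectra of food samples by species and geographical
    origin. Implements technique-specific preprocessing (region selection,
    Savitzky-Golay smoothing and derivatives, multiplicative scatter correction,
    integral normalisation, uniform binning, train/test-safe autoscaling), an
    orthogonal signal correction filter, PCA-based outlier rejection via the 95%
    Hotelling T-squared limit, PLS-DA and oPLS-DA classifiers built by NIPALS,
    and a validation battery: Q2 statistics under stratified k-fold and Monte
    Carlo cross-validation, pooled ROC curves and per-model AUC distributions,
    and loading-stability analysis. A seeded synthetic-spectra generator with
    planted class effects, scatter, confounders and outliers makes every stage
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    knitr,
    mixOmics,
    optparse,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
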