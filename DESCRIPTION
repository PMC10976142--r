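Package: ephah
Title: Exhaustive Half-Against-Half PLS-DA for Large-Class NIR Spectral
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric toolkit for classifying near-infrared (NIR)
    diffuse-reflectance spectra into many classes. Implements the
    exhaustive, parallel half-against-half (EPHAH) multiclass
    decomposition with maximum-win voting, alongside one-against-one and
    one-against-all baselines, on NIPALS PLS-DA binary classifiers.
    Supporting stages cover robust-PCA outlier screening with score and
    orthogonal distances and F-based cutoffs, Kennard-Stone, SPXY,
    stratified DUPLEX and random sample-set partitioning, composable
    spectral pretreatments (Savitzky-Golay smoothing and derivatives,
    SNV, MSC), synergy-interval PLS (SI-PLS) characteristic-interval
    selection, Monte Carlo cross-validation for latent-variable choice,
    and a seeded generator of class-structured synthetic NIR spectra for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
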