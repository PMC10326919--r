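Package: easispec
Title: Expert Algorithm for Substance Identification from Replicate EI Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identification of compounds from unit-resolution electron-ionization
    mass spectra using per-fragment-ion general linear models (EASI). Replicate
    training spectra of a target compound are used to fit one stepwise linear
    model per panel ion, so that each ion's abundance in a query spectrum is
    predicted from the other ions measured in that same spectrum. Residuals
    between predicted and measured abundances feed a suite of spectral
    similarity and dissimilarity measures (mean absolute residual, Euclidean
    distance, cosine dot product, weighted NIST-style match score), a
    covariance-based Mahalanobis distance with a chi-square outlier test, and
    binary classifiers (threshold sweeps, ROC/AUC, precision-recall, stepwise
    logistic regression on residuals). Includes MSP and CSV readers/writers,
    a synthetic replicate-spectrum generator with a latent instrument-state
    factor for method evaluation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
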