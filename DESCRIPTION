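Package: mixlta
Title: Mixture Latent Trait Models for the Self-Administered Child Food
    Security Scale
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimation and validation toolkit for dichotomous food-security
    scales measured on children. Fits latent class analysis (LCA), Rasch
    latent trait analysis (LTA) and mixture latent trait analysis (MLTA,
    i.e. mixture IRT) models to a 9-item binary response matrix by marginal
    maximum likelihood with Gauss-Hermite quadrature and an EM algorithm
    with multiple random starts. Provides model comparison (AIC, BIC,
    sample-size-adjusted BIC, relative entropy, bootstrapped likelihood
    ratio test), posterior classification and prevalence estimation,
    response-pattern goodness of fit, differential item functioning and
    per-item threshold-invariance scans, a CART classification tree for
    raw-score cut-off derivation, and a synthetic-data generator for the
    two-class mixture IRT population used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
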