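Package: pglsverse
Title: Multiverse Stability Analysis for Phylogenetic Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exhaustive model-stability ("multiverse") analysis for
    phylogenetic generalized least squares (PGLS). Fits every subset of
    candidate predictors against one or more trait outcomes on a phylogeny
    under a Pagel's-lambda transformed Brownian-motion covariance, selects
    models by AIC, and summarises how each predictor's estimate and p-value
    move as concomitant predictors change. Includes collinearity diagnostics
    (OLS and whitened-design variance inflation factors, partial R-squared,
    conjugate posterior slope correlations), weighted pooling of multi-source
    trait tables with the standard comparative transforms, and a synthetic
    data generator producing phylogenetically structured, collinear
    predictors with known coefficients so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nlme,
    withr
Config/testthat/edition: 3
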