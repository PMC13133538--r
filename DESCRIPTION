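Package: hyperdim
Title: Transdiagnostic Hyperarousal Dimensions from Ordinal Questionnaire Batteries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to decompose large batteries of ordinal (Likert-type)
    questionnaire items into latent hyperarousal dimensions and to carry the
    dimensions into external cohorts. Implements two-step maximum-likelihood
    polychoric correlation with continuity correction and eigenvalue smoothing,
    Kaiser-Meyer-Olkin sampling-adequacy screening, stepwise redundancy
    reduction of near-duplicate items, parallel analysis, principal-axis
    factoring with promax rotation, loading-weighted and short-form (0-4)
    dimension scoring, congeneric and higher-order confirmatory factor models
    with likelihood-ratio comparison, Cronbach's alpha and McDonald's omega,
    standardized regression profiles of disorder severity on dimensions,
    EBIC-regularized partial-correlation networks with bootstrap edge
    thresholding, and Dwyer factor extension for indicator measures. A fully
    specified latent-factor simulator provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    mvtnorm,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
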