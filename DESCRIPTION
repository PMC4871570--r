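Package: elevcomm
Title: Community Analysis of Flightless Insect Assemblages Along Elevational Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for elevationally stratified community data
    such as pitfall-trap catches of flightless ground beetles: individual- and
    coverage-based rarefaction with extrapolation, negative-binomial GLM and
    GLMM trend models, Bray-Curtis dissimilarity with a dummy-species
    convention for depauperate samples, NMDS ordination with environmental
    vector fitting, distance-based PERMANOVA with sequential sums of squares
    and permutation of residuals under a reduced model, correlation-based
    predictor screening, and exhaustive AICc model averaging that ranks
    environmental predictors by summed Akaike weight against a permutation
    null (standardised effect sizes and permutation P values). Includes a
    synthetic-data generator reproducing the sampling design and statistical
    structure of a multi-subregion elevational field survey, so the full
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    vegan,
    lme4,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    glmmTMB
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
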