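Package: geobiodiv
Title: Geodiversity Compound Indices Versus Environmental Predictors of
    Biodiversity and Ecosystem Functions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for testing whether a compound geodiversity index - the
    summed Shannon diversity of classified environmental rasters in a plot's
    3x3 pixel neighbourhood - predicts taxon Shannon diversity and ecosystem
    functions as well as the plot-level environmental variables themselves.
    Implements Fisher's optimal (natural-breaks) interval classification,
    neighbourhood class-diversity extraction, coverage-based standardization
    of taxon Shannon diversity to the asymptote, generalized additive model
    fitting with explained deviance, three-set variance partitioning by
    inclusion-exclusion, AIC and collinearity predictor-selection rules, and
    a synthetic elevational-gradient landscape generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
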