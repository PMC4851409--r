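Package: nichenull
Title: Standard and Environmentally Constrained Null Models for Species
    Co-Occurrence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare segregation (checkerboard units, C-score) and
    nestedness (NODF) of a binary site-by-species community matrix against
    ensembles of pseudo-communities from standard null models (fixed
    occurrences with equiprobable sites; fixed-fixed trial-swap chains) and
    environmentally constrained null models built from leave-one-out niche
    predictions (stepwise-AIC logistic regression and random forests), with
    fixed-richness and fully probabilistic drawing schemes. Includes
    group-partitioned checkerboard statistics, distance-based redundancy
    analysis of community composition on environmental predictors, and a
    synthetic metacommunity generator with known niche structure and a
    tunable mass-effect mechanism for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    randomForest,
    stats,
    utils,
    vegan,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
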