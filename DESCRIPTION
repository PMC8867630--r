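Package: polysub
Title: Semi-Supervised Max-Margin Polytope Subtyping of Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers disease subtypes in case-control neuroimaging cohorts by
    fitting K max-margin hyperplanes that form a convex polytope separating
    controls from patients, assigning patients to faces of the polytope.
    Provides cross-validated consensus clustering with adjusted-Rand-index
    model selection, split-half and leave-one-site-out reproducibility
    harnesses, covariate (age and site) residualization, subtype-level
    clinical statistics with FDR control, sliding-window dynamic time-series
    measures with Kendall-W concordance, balanced nested cross-validated
    linear SVM classification, and a synthetic cohort generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    e1071,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
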