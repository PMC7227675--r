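Package: garpui
Title: Rule-Based Niche Models, Variable Contribution via the Unimportance Index, and Virtual-Species Benchmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Presence-only ecological niche modelling with a genetic algorithm
    for rule-set production (range, negated-range, logit and atomic rules,
    internal chi-square rule testing, best-subset selection by omission and
    commission), estimation of per-variable contributions from the dominant
    presence rules of a best subset via the Unimportance Index (prevalence,
    median range, rescaled UI), a virtual-species simulator on spatially
    autocorrelated Gaussian random field landscapes (exponential and spherical
    variograms, circulant embedding), and a validation harness that scores
    how often the three lowest-UI variables recover the true drivers against
    a hypergeometric random-draw null with chi-square goodness-of-fit and
    homogeneity tests. Includes accuracy metrics (omission, commission,
    ROC/AUC with Hanley-McNeil standard errors) and ESRI ASCII grid I/O.
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
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
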