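Package: corrnull
Title: Correlation-Informed Null Models for Binary Incidence Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing structural patterns in binary incidence
    matrices (species-by-site assemblages, directed food webs) against
    uninformed, correlation-informed, and misinformed fixed-fixed null
    models. Per-link probabilities are estimated from an incidence matrix
    and a correlation matrix (phylogenetic, spatial-exponential, group, or
    constant) by row-wise mixed-effects logistic regression with a Laplace
    approximation; the estimated probabilities bias a marginal-preserving
    swap randomization. Structural patterns (three-node motif censuses,
    NODF nestedness) are scored with z-scores against the resulting
    ensembles. Includes generators for phylogenetically structured
    synthetic food webs and nested species assemblages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
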