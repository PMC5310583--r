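Package: corrtrait
Title: Correlated Evolution of Binary Traits on Phylogenies
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maximum-likelihood tools for testing correlated evolution of two
    binary traits on a phylogeny. Implements the four-state dependent and
    independent continuous-time Markov models for trait pairs, exact
    log-likelihoods by Felsenstein pruning with a compiled core, multi-start
    model fitting with chi-squared likelihood-ratio tests (including
    single-constraint restricted-rate models), marginal ancestral-state
    reconstruction with proportional likelihoods and transition counting,
    maximum clade credibility tree selection from posterior tree samples, and
    a seeded Yule-tree and Gillespie trait simulator with ground-truth event
    logs for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phytools,
    phangorn,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
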