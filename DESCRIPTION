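Package: plastnet
Title: Individual Plasticity in Animal Social Network Phenotypes
Version: 0.1.0
Authors@R:
    person("Lighthouse", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how individual social network phenotypes
    (strength, weighted clustering coefficient, size-corrected closeness)
    respond to environmental variation in fission-fusion animal societies
    observed by photo-identification. Builds weighted social networks from
    grouped encounter records via the gambit of the group and the simple
    ratio association index, computes node-level traits per yearly or
    monthly window, and fits random-regression (reaction norm) linear
    mixed models by maximum likelihood with correlated individual
    intercepts and slopes, first-order autoregressive year effects and
    month effects. Includes the boundary-aware likelihood-ratio testing
    hierarchy for intercept-slope correlations and random slopes,
    marginal and conditional repeatability, and a synthetic-data
    generator emulating multi-decade boat survey designs so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    graphics,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
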