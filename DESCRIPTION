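Package: herbcascade
Title: Hierarchical Bayesian Modelling of Climate-Soil-Foliage-Herbivory Cascades
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying insect herbivory across abiotic gradients with a
    three-tier hierarchical Bayesian model: climate and geology drive soil
    chemistry, soil chemistry and climate drive foliar nutritional chemistry,
    and all of these drive tree-level herbivory pressure modelled with a beta
    likelihood. Includes a synthetic-landscape generator with known ground
    truth, measurement arithmetic for digestibility indices and leaf-damage
    aggregation, an adaptive Metropolis-within-Gibbs sampler written in C++,
    convergence and posterior-predictive diagnostics, and posterior summaries
    of direct and indirect (path) effects with equal-tailed credible intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
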