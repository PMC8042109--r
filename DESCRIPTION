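Package: sciurognath
Title: Phylogenetic Comparative Analysis of Brain Size and Locomotion in
    Squirrels and Relatives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for phylogenetic comparative analysis of
    endocast measurements in sciuromorph rodents: stochastic fossil
    time-calibration of a fixed topology, phylogenetic generalized least
    squares under Brownian, Pagel's lambda, early-burst and
    Ornstein-Uhlenbeck covariance models with AIC selection, a
    phylogenetically derived encephalization quotient, asymptotic
    Fisher-Pitman permutation tests with Benjamini-Hochberg adjustment,
    residual-randomization ANOVA with post-hoc pairwise comparisons, and
    maximum-likelihood ancestral reconstruction of continuous traits plus
    stochastic character mapping of a five-state locomotor character.
    Includes a synthetic-data generator that emulates the study design so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phytools,
    jsonlite
Config/testthat/edition: 3
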