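Package: pmkinetics
Title: Grouping, Normalization and Bayesian Effect Identification for
    Phenotype MicroArray Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-stage analysis pipeline for Biolog Phenotype
    MicroArray (PM) kinetic data. Well-level respiration profiles are
    classified as active or non-active with a hard-assignment EM
    algorithm over a logistic/linear mixture; systematic multiplicative
    array effects are removed by normalizing replicate plates against a
    reference array using group-specific base curves; and differences
    between experimental conditions are quantified with a Bayesian
    hierarchical two-factor variance analysis with interaction, sampled
    by an internal Gibbs sampler. Includes a synthetic-data generator
    for factorial PM experiments with known ground truth, and a
    command-line interface over the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
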