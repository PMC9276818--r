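Package: twinbelief
Title: Twin-Design Heritability Analysis of Belief-Formation Task Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the heritability of cognitive and affective
    phenotypes derived from a multi-trial belief-updating task administered to
    monozygotic and dizygotic twin pairs. Computes trial-derived scores
    (belief update, learning score, memory score, subjective-rating means,
    priors), assesses twin similarity with permutation partial correlations
    over random twin A/B reassignments, and decomposes phenotypic variance
    into additive genetic, dominance, shared-environment and unique-environment
    components by maximum likelihood (ACE/ADE model families) with AIC model
    comparison and profile-likelihood confidence intervals. Includes a
    synthetic twin-cohort generator with known variance-component ground truth
    so the full analysis chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
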