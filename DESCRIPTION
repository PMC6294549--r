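Package: startlecircuit
Title: Whole-Body Startle-Response Circuit and Behavior Analysis for Annelid Larvae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing a hydrodynamic startle response in planktonic
    annelid larvae across four data modalities: seed-based extraction of the
    sensory-motor circuit from synapse-level connectome tables (inclusion,
    bilateral-rescue, exclusion and grouping rules), directed-graph motif
    readouts (fewest-synapse sensorimotor pathways, shared-target convergence,
    laterality, bilateral symmetry, segmental profiles), two-component
    truncated-Gaussian mixture classification of parapodial elevation angles
    with a bootstrap cutoff interval, ratiometric two-channel calcium-trace
    quantification, and paired predation-rate statistics with an exact
    one-sided Wilcoxon-Pratt signed-rank test. A synthetic-data module
    generates bilaterally symmetric layered connectomes, bimodal behavioral
    trials, drift-contaminated fluorescence traces and paired predation
    experiments with recorded ground truth, so every stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
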