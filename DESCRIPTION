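Package: cleavent
Title: Cleavage Entropy Profiling of Protease Substrate Specificity
Version: 1.0.0
Authors@R:
    person("Cleavent", "Developers", email = "cleavent@example.org",
           role = c("aut", "cre"))
Description: Quantifies protease substrate specificity from tables of
    experimentally observed cleavage-site sequence windows using
    information entropy. Computes subpocket-wise cleavage entropies
    (Schechter-Berger positions P4 to P4') from natural-abundance
    normalized amino-acid probability matrices, their sum as a total
    cleavage entropy on a 0-8 scale for ranking proteases, and pairwise
    (joint) cleavage entropies between subpockets to detect cooperative
    substrate readout. Includes seeded synthetic substrate generators
    with exact expected-count allocation for analytic endpoint testing,
    specificity classification at configurable thresholds, group
    summaries, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    optparse,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
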