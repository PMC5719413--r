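Package: recallnet
Title: Mechanistic Simulation of Human Recall of Signed Social Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study how people reconstruct a social network from
    memory. Implements a seeded stochastic recall model in which ties
    incident to a few well-remembered characters are recalled exactly and
    the remainder of the network is reconstructed with compression
    heuristics: triadic closure driven by the target network's closed/open
    triplet ratio, a density-based background probability for non-closing
    pairs, a structural-balance sign-product rule for the affect (valence)
    of reconstructed ties, a positivity bias for ties without triadic
    context, and partial corruption of initially recalled valences.
    Includes a constrained generator for two-component signed stimulus
    networks in balanced and imbalanced valence configurations, evaluation
    metrics (precision, coverage, quality, and a standardised deviation
    against experimental summaries), and reproducible Monte Carlo sweeps
    over seed sets, closure mis-recall, and valence-corruption rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
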