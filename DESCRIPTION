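Package: seednet
Title: Seed-Based Protein-Protein Interaction Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses seed-based protein-protein interaction (PPI)
    networks for candidate drug-target prioritization. Provides confidence
    filtering and zero-/first-order network construction from scored edge
    tables, network topography statistics and hub/non-hub-bottleneck backbone
    extraction, Markov clustering (MCL) with inter-cluster switch detection,
    MCODE molecular complex detection, gene-set over-representation analysis
    (accumulative hypergeometric tests with Benjamini-Hochberg correction,
    fold enrichment, strength, and kappa-score term clustering), and a
    synthetic two-community network generator with planted bridges and
    enriched gene sets so every stage is testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
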