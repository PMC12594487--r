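Package: hmgm
Title: Hidden Markov Graph Models of Dynamic Brain States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits condition-specific Gaussian hidden Markov models to
    multi-subject ROI BOLD time series, quantifies sink-state dominance and
    temporal complexity of the fitted Markov chain (stationary 'sink'
    centrality, switching rate, entropy rate, occupancy entropy), builds the
    hidden Markov graph model (HMGM) -- a multilayer graph with brain states
    as layers, functional-connectivity edges within layers, and
    transition-probability coupling between layers -- detects spatiotemporal
    communities by consensus generalized Louvain, and compares dynamic
    functional organization against a weighted structural connectome
    (distance correlation, adjusted mutual information, efficiency, rank and
    permutation tests). A seeded synthetic-cohort generator with planted
    states, sink dynamics, and block communities provides ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    mclust,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
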