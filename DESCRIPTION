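Package: rwacd
Title: Seed-Expanding Community Detection via Personalized Random Walks
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects communities in undirected simple networks, including
    networks with ambiguous (weak) community structure, by growing dense
    seed subgraphs around local maximal degree hubs with personalized
    random walks over a structural-similarity transition matrix, followed
    by tightness-based assignment of leftover nodes and overlap-driven
    merging.  Ships planted-partition benchmark generators (equal-group
    GN graphs and LFR graphs with power-law degrees and community sizes),
    partition-comparison metrics (normalized mutual information and
    best-match F1), a strong/weak community classifier, and a small
    command-line driver for reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
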