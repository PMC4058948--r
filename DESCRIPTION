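Package: netreach
Title: Exact Signal Reachability in Probabilistic Directed Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Exact computation of the probability that a signal originating
    at a source node reaches a target node in a directed network whose edges
    exist independently with given probabilities (two-terminal network
    reliability). The core algorithm partitions the network along a sequence
    of good node separators and folds a sparse edge-aggregation polynomial
    across the stages, collapsing terms whose reachability outcome at the
    next separator is determined; this keeps the polynomial small while the
    result remains exact. The package also provides two independent
    reference oracles (exhaustive configuration enumeration and
    inclusion-exclusion over simple paths), reachability profiles over
    source/target sets, node-removal centrality, perturbation-stability
    analysis, a Barabasi-Albert synthetic network generator, edge-list I/O
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    optparse,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
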