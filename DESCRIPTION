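Package: syndromirnet
Title: Serum miRNA Profiling of Disease Syndromes via Moderated Tests,
    Target Consensus and Weighted miRNA-Target Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for small-sample serum miRNA array
    studies comparing several patient subgroups against a common control
    group. Implements the random-variance-model (RVM) moderated t-test
    with a fold-change filter for differential expression, hierarchical
    clustering with a one-minus-correlation metric and average linkage,
    SVM binary-tree class prediction with cross-validated node scores,
    a multi-program miRNA target-prediction consensus rule (pairwise
    vote among nine binary predictors intersected with a score-valued
    predictor), node-weighted bipartite miRNA-target network
    construction with hub and up-regulated subnetwork extraction and
    rank-based cross-network comparison, and local hypergeometric
    gene-set over-representation analysis with FDR control. Ships a
    synthetic-data generator with known ground truth so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    e1071,
    igraph,
    ape,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
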