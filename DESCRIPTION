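Package: dynppin
Title: Protein Complexes and Functional Modules from Dynamic
    Protein-Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds a dynamic protein-protein interaction network by
    thresholding time-course expression profiles into a series of
    time-sequenced subnetworks (TSNs), detects protein complexes in each
    TSN by edge-clustering-value driven hierarchical agglomeration
    (lambda-module locking), and groups the detected complexes into
    functional modules by greedy modularity-gain seed extension on a
    complex-complex interaction network whose edges encode temporal
    synchrony/adjacency and membership similarity. Includes overlap-score
    benchmarking against gold-standard catalogues (sensitivity,
    specificity, f-measure), complex frequency summaries, hypergeometric
    GO enrichment screening of modules, and a fully synthetic fixture
    generator with planted complexes and known activity windows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
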