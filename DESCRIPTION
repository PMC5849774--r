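Package: glycodim
Title: Finite Dimension and Glycan Space Analysis of Glycan Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes the finite dimension of glycan graphs, a metric-space
    adaptation of the Hausdorff dimension to finite graphs, defined as
    ln(N)/ln(D) where N is the minimum clique cover number of the vertex set
    and D the graph diameter.  Provides the Glycan Space encoding that maps
    every glycan graph to a point (dimension, diameter) of the plane,
    structural classification of glycan graphs (linear, branched, cyclic),
    closed-form dimensions for standard graph families, universal bounds and
    diameter-line thresholds, a synthetic glycogen simulator producing
    branched caterpillar trees, AHU tree canonicalization with
    isomorphism-class counting, a code-then-isomorphism database search, and
    a taxonomy dimension-exclusivity analysis.  Includes a command-line
    interface for batch processing of edge-list files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
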