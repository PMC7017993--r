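Package: fdconn
Title: Fractal Dimension Analysis of Functional Connectivity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates fractal dimensions of brain functional connectivity at
    three levels: the network box-counting dimension of thresholded binary
    correlation graphs via the stochastic Compact Box Burning algorithm, a
    two-dimensional box-counting dimension of the adjacency matrix rendered as
    a binary image, and the Higuchi fractal dimension of regional time series.
    Includes construction of binarized functional connectivity graphs from
    ROI time-series tables (Pearson correlation, self-loop removal, rank-based
    percentile thresholding, negative-edge discard), null-model batteries
    (k-nearest-neighbour ring and grid lattices, edge-matched uniform random
    graphs), nonparametric group statistics (Kruskal-Wallis, Mann-Whitney U,
    Benjamini-Hochberg false discovery control), and synthetic generators with
    known fractal dimension ((u,v)-flower graphs, exact fractional Brownian
    motion, hierarchical-modular multi-subject cohorts) for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    methods,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    png,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
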