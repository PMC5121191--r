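Package: covgraph
Title: Covariance and Concentration Graph Reconstruction Benchmarks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the relation between covariance graphs
    (marginal dependence, including transitive indirect edges) and
    concentration graphs (conditional dependence) in Gaussian graphical
    models.  Provides transitive-closure algebra linking the two graph
    types, network deconvolution operators with closed forms for chain
    graphs via the Kac-Murdock-Szego matrix, synthetic data generation
    from chain, cluster, scale-free and hub topologies, five sparse
    graph estimators (hard-thresholded covariance with a scale-free
    selection criterion, covariance Lasso via majorization-minimization,
    nodewise regression Lasso, graphical Lasso, adaptive Lasso) and an
    evaluation harness for high-dimensional (p > n) reconstruction
    benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
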