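Package: structcoef
Title: Structural Similarity and Complementarity Coefficients for Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Exact edge-level census of triangles, triples, chordless
    quadrangles and quadruples in simple undirected graphs, and the family
    of structural similarity (triangle-based) and complementarity
    (quadrangle-based) coefficients built on top of it, at the edge, node
    and graph level. Includes deterministic and geometric (sphere-model)
    graph generators, a maximum-entropy configuration null model (UBCM)
    with exact expected-degree fitting and sampling, log-ratio calibration
    of graph statistics, degree-bucketed one-sided significance testing
    with two-stage FDR correction, and an entropy-based structural
    diversity index. A command-line interface wires the pieces into
    reproducible runs on plain-text edge lists.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    vegan,
    withr
Config/testthat/edition: 3
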