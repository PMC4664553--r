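Package: pfnet
Title: Planar Filtered Co-Expression Networks with Multiscale Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Constructs planar filtered co-expression networks (PFNs) from gene
    expression matrices by embedding rank-ordered gene pairs subject to a
    planarity constraint (planar maximally filtered graphs), with a batched
    screening procedure and early-termination rules for large inputs.
    Decomposes the resulting network into a multiscale cluster hierarchy via
    divisive k-medoids clustering on shortest-path distances with local-path-
    index boundary correction, scores cluster compactness across resolution
    scales against random planar null models, identifies per-scale and
    multiscale hub genes, and associates clusters with sample traits and
    survival outcomes through module eigengenes.  Includes a synthetic-data
    generator with planted module structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    cluster,
    survival,
    Matrix,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
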