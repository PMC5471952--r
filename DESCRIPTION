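Package: sanjay
Title: Decision-Procedure Synthesis of Low-Distortion Embeddings for Flow Cytometry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthesizes two- and three-dimensional embeddings of
    high-dimensional flow cytometry data by iterative bit-vector refinement:
    pairwise distances are quantized onto an integer grid and coordinates are
    fixed a few high-order bits at a time, each step solved as a decision
    problem that keeps every pair's reachable squared distance inside a
    multiplicative tolerance band. The supporting pipeline builds a thresholded
    cell-similarity network (threshold chosen by degree-entropy maximization),
    partitions it into communities by random-walk agglomeration, summarizes
    each community by its centroid and k-means component centroids, and places
    every remaining cell by least-squares trilateration against its
    community's embedded anchors. Includes distortion-based evaluation against
    classical multidimensional scaling and Gaussian random projections, a
    Gaussian-mixture generator of cytometry-like point clouds, an exhaustive
    brute-force oracle for small instances, and readers for FCS 3.0/3.1 and
    delimited event tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
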