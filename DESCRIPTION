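Package: saless
Type: Package
Title: Resolution of Tree Shape Statistics on NNI Tree Space
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluates the discriminatory power of tree shape statistics over
    the complete space of unlabeled rooted bifurcating tree shapes on a fixed
    number of leaves. Enumerates all shapes, builds the Cayley graph of
    nearest-neighbour-interchange (NNI) moves, and scores statistics (Colless,
    Sackin, depth variance, I2, B1, B2, cherries) by a distance-based
    resolution over squared NNI distances or by a Laplacian (Dirichlet-energy)
    resolution, each rescaled to the unit interval by extreme
    Rayleigh-quotient eigenvalues. Computes optimal linear combinations of two
    statistics in closed form, including the Saless index (a combination of
    Sackin and Colless), classical multidimensional-scaling embeddings of tree
    space, and random tree shapes under the Yule and PDA models.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    graphics,
    Matrix,
    igraph,
    ape,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
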