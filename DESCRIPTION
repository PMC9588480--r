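Package: somaspat
Title: Three-Dimensional Spatial Point-Pattern Analysis of Neuronal Soma
    Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the three-dimensional spatial organisation of
    neuronal cell bodies from microscopy-derived coordinates. Implements
    bounded 3D region geometry (convex hulls and alpha-complexes built on an
    internal Delaunay tetrahedralisation, voxel masks, analytic shapes),
    uncorrected homogeneous and inhomogeneous Ripley K-functions with Monte
    Carlo null envelopes (optionally honouring axonal-bundle exclusion zones),
    Gaussian kernel intensity estimation with Silverman bandwidths, the Illian
    F-test for density homogeneity, nearest-neighbour distance profiles and
    nearest-neighbour-graph cluster analysis, voxel-clipped 3D Voronoi
    volumetrics, hemispheric density summaries, and a synthetic-data generator
    that emulates per-region counts, volumes, anterior-posterior density
    gradients, Thomas-clustered alternatives and tube-like fibre-bundle
    exclusion zones.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    FNN,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
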