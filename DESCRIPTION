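Package: cloudvol
Title: Point-Cloud Surface Reconstruction and Volume-Based Livestock Weight Estimation
Version: 0.1.0
Authors@R:
    person("cloudvol", "developers", email = "cloudvol@example.org", role = c("aut", "cre"))
Description: Tools for estimating the volume of animals (and other closed
    objects) from 3D surface point clouds. Implements moving-least-squares
    point-cloud smoothing, PCA normal estimation with maximum-spanning-tree
    orientation propagation over a KNN graph (with tangency-corrected edge
    weights), screened Poisson surface reconstruction discretized over an
    octree-backed grid with dynamic per-sample confidence weights, watertight
    isosurface extraction, signed tetrahedral mesh volume, a slicing-method
    baseline, and a linear volume-to-body-weight regression model with error
    diagnostics. Includes synthetic shape generators (cube, cylinder, sphere,
    L-prism, thin plate, piglet composite) with analytic or constructive
    ground-truth volumes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
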