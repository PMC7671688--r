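Package: confluence
Title: Continuous Iso-to-Allocortical Surface Modelling and Multiscale
    Analysis of the Mesiotemporal Lobe
Version: 0.1.0
Authors@R:
    person("Confluence", "Developers", email = "confluence@example.org",
           role = c("aut", "cre"))
Description: Builds a continuous surface model of the mesiotemporal cortical
    confluence by stitching isocortical and allocortical (hippocampal) surface
    meshes at the subicular bridgehead, maps a signed geodesic
    iso-to-allocortical axis over the joint mesh, samples depth-wise
    microstructure profiles along equivolumetric intracortical surfaces,
    extracts cytoarchitectural gradients via microstructure profile covariance
    and diffusion map embedding, predicts axis position from profile features
    with random forest regression, estimates directed (effective) connectivity
    between axis bins from a linear stochastic model of fMRI timeseries, and
    relates axis position to macroscale functional gradients with
    spin-permutation inference. A fully synthetic data generator with known
    ground truth (confluent toy meshes, intensity volumes, stochastic linear
    dynamics, low-rank parcel connectomes on the sphere) makes every pipeline
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    xml2
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
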