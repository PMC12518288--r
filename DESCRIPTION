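Package: sricp
Title: Marker-Based Multi-View Point Cloud Registration and Plant Phenotyping
Version: 0.1.0
Authors@R: person("sricp", "developers", role = c("aut", "cre"),
    email = "sricp@example.org")
Description: Registers multi-view 3D point clouds of potted plants into a
    single metric model and extracts morphological traits. Per-view colored
    point clouds (PLY) are cleaned by color thresholding and statistical
    outlier removal, rescaled to a common metric scale from the fitted pot-rim
    circle, and aligned by a marker-based self-registration step: six colored
    calibration spheres are localized per view with an enhanced RANSAC sphere
    fit (dynamic inlier threshold, weighted scoring, geometric constraints,
    Levenberg-Marquardt refinement), homonymous sphere centers yield SVD rigid
    transforms that are chained to the reference view and refined by
    point-to-point ICP. Plant height, crown width, leaf length and leaf width
    are measured on the merged model. A synthetic multi-view scene generator
    with full ground truth supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
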