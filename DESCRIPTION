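Package: gaitstream
Title: Two-Stream Spatial-Temporal Gait Classification for Quadrupeds
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies quadruped (felid) video clips into three gaits
    (standing, ambling, galloping) with a two-stream architecture: a
    spatial stream that extracts the animal's outline from binary
    instance masks and classifies 112x112 contour rasters with a small
    VGG-style convolutional network, and a temporal stream that computes
    per-frame knee-joint bending angles from 18 tracked body landmarks
    and classifies the (front, hind) angle time series with an LSTM.
    Class scores from the two streams are combined by a convex weighted
    average. Includes a seeded kinematic stick-figure simulator that
    generates labelled pose sequences and silhouette masks emulating the
    per-gait knee-angle regimes, plus readers/writers for keypoint
    CSV/JSON, HDF5 clip bundles and PNG masks, an evaluation module
    (per-class accuracy, confusion matrix) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    jsonlite,
    png,
    Rcpp,
    rhdf5,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
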