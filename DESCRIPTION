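Package: occrnn
Title: Recurrent Convolutional Networks for Stereoscopic Occluded Object Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to study how recurrent connectivity helps convolutional
    networks recognize partially occluded objects. Provides a stereoscopic
    2.5D scene simulator that composites class-labelled glyphs at different
    depths with binocular disparity and per-pixel segmentation, a family of
    feedforward and recurrent convolutional classifiers (bottom-up, lateral,
    top-down connectivity) unrolled through time and trained with truncated
    backpropagation through time, paired model comparison via McNemar's test
    with false-discovery-rate control, introspection of the learned
    representation (class activation maps, Gini concentration, latent
    distances to unoccluded class centroids), and quantification of
    perceptual hysteresis on bistable class-to-class morph sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
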