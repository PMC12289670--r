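Package: strawyolo
Title: Growth-Stage Detection and RGB-D Localization of Strawberries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A single-stage anchor-free object-detection toolkit for monitoring
    the four growth stages of strawberry (bud, flower, under-ripe fruit, ripe
    fruit) in orchard imagery, with RGB-D back-projection of detections to
    camera-frame 3D coordinates. Implements a YOLOv8-family detector (CSP
    backbone, path-aggregation neck, decoupled distribution-regression head)
    together with two channel-attention extensions: a squeeze-and-excitation
    enhanced multi-scale depthwise strip-convolution block (SE-MSDWA) inserted
    at the end of the backbone, and a context-guided fusion module (CGFM) that
    replaces channel concatenation in the neck with multi-head self-attention
    gated mixing. Training uses a warmup schedule that ramps data-augmentation
    probabilities over the first fifth of the epochs. Includes exact analytic
    parameter accounting for every architecture variant, COCO-style mAP
    evaluation, class-wise non-maximum suppression, and a synthetic-scene
    generator producing RGB images, aligned depth maps and YOLO-format labels
    with known 3D ground truth. The network forward and backward passes are
    implemented natively (RcppArmadillo convolution kernels plus reverse-mode
    automatic differentiation), so the toolkit has no deep-learning framework
    dependency.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    yaml,
    jsonlite,
    stats,
    grDevices,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
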