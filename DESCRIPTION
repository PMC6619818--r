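Package: HexGait
Title: Self-Training Leg Tracking and Gait Analysis for Walking Arthropods
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Locates and tracks the leg claws of a freely walking hexapod (or
    arachnid) in high-speed backlit silhouette video without any hand-annotated
    training data. Training examples are harvested from the video itself by
    intersecting skeleton and edge morphology of the animal silhouette, a
    boosted ensemble of decision trees with learned convolution-kernel split
    features is fit to those examples, and the resulting pixel classifier
    segments legs frame by frame. Claw positions are then tracked across frames
    by gated Hungarian assignment, and a full suite of body, stride, leg-domain,
    gait-index, tremor and effect-size statistics is computed from the tracks.
    Includes a deterministic synthetic walker renderer with per-pixel ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    png,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
biocViews: Software, CellBiology, Classification, Segmentation, Tracking
Config/testthat/edition: 3
RoxygenNote: 7.3.3
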