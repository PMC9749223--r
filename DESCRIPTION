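Package: wormplate
Title: Plate-Level Tracking and Posture Analysis for Long-Term C. elegans
    Behavioral Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying Caenorhabditis elegans population behavior
    from long-term plate-level timelapse recordings. Implements the full
    chain from raw grayscale frames to behavioral summaries: temporal-median
    background subtraction and size-selected segmentation, gap-free
    nearest-neighbor track linking, kinematics (speed and angular velocity)
    in 10-second bins, morphological skeletonization with motion-based head
    assignment, 24-dimensional intersegment-angle posture vectors, eigenworm
    decomposition, k-means posture libraries with mirror-pair merging and
    meta-posture grouping, time-resolved posture-abundance z-scores,
    dispersal/quiescence state classification, and random-forest turn
    detection from bitmask shape features. A synthetic plate simulator with
    full ground truth (positions, midlines, behavioral states) makes every
    stage testable without a microscope.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    EBImage,
    randomForest,
    jsonlite,
    yaml,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, CellBiology, BehavioralGenomics, Visualization
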