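Package: leaftracker
Title: Leaf Instance Tracking and Photosynthesis Trait Extraction for
    Top-View Plant Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detector-agnostic reconstruction of individual leaf tracks
    from per-frame instance segmentation masks of top-view plant images,
    using greedy intersection-over-union (IoU) association between
    consecutive timepoints with carry-forward of missed detections.
    Includes frame-level detection and segmentation scoring (precision,
    recall, F-score, matched-pair IoU descriptors), tracking-quality
    evaluation with the Higher Order Tracking Accuracy (HOTA) metric and
    whole-track right/miss verdicts, per-leaf extraction of chlorophyll
    fluorescence traits (Fv/Fm, PhiPSII) from parameter images, and a
    seeded synthetic rosette generator producing ground-truth tracks,
    noisy detections and trait images for benchmarking.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    png,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
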