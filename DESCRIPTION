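Package: hooploc
Title: Video-Based 3D Localization of Multiple Basketball Players
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Markerless 3D localization of basketball players from
    synchronized multi-camera video. Provides direct linear transformation
    (DLT) camera calibration and triangulation, per-camera head detection
    (adaptive mixture background segmentation with shadow relabeling,
    contour maxima, circle Hough fitting, histogram-of-oriented-gradients
    features and a multilayer-perceptron head classifier), a constrained
    combinatorial assignment of detected head points to players solved by
    a greedy round heuristic with a fixed-mean-height fallback, a synthetic
    multi-camera scene simulator for fully reproducible experiments, and
    the matching-based evaluation protocol (detection rates and planar /
    spatial localization RMSE).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    mgcv,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nnet,
    withr
Config/testthat/edition: 3
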