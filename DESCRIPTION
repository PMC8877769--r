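Package: fetalhc
Title: Fetal Head Circumference Estimation from Ultrasound-Like Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate the fetal head circumference (HC) biomarker from
    two-dimensional ultrasound-like images by two routes: a segmentation route
    (segment the skull, post-process the mask with Canny edge detection and
    largest-connected-component filtering, fit an ellipse, and measure its
    perimeter with the Ramanujan approximation) and a direct regression route
    (a miniature convolutional network trained with MAE, MSE or Huber losses).
    Includes a synthetic phantom generator producing elliptical skull images
    with analytically known HC and per-image pixel spacing, segmentation
    evaluation metrics (Dice, Hausdorff, average symmetric surface distance),
    HC error metrics (MAE, percentage MAE), Bland-Altman and linear-regression
    agreement analysis with paired t-tests, a reproducible cross-validated
    experiment runner, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
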