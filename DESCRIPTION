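Package: mbwm
Title: Model-Based Wear Measurement of Knee Implant Inlays from Plain Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for estimating the minimum joint space width (mJSW) and
    linear polyethylene wear of total knee arthroplasty inlays from single
    calibrated plain radiographs. Implements silhouette-based 2D-to-3D pose
    registration of implant surface models (downhill simplex with simulated
    annealing acceptance), a virtual flat-panel calibration model, Canny-based
    sub-pixel contour extraction, closest-point mJSW and wear computation with
    a peripheral-rim correction, a simulated coordinate-measurement-machine
    ball-probe reference, a parametric phantom generator producing synthetic
    radiograph studies with ground truth, and the accompanying validation
    statistics (measurement error, mean absolute error, Bland-Altman limits
    of agreement, paired t-tests, one-way ANOVA, and profilometric roughness
    metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    optparse
Config/testthat/edition: 3
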