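Package: RGDetect
Title: Retinal Microaneurysm Detection with Ring Gradient Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detection of retinal microaneurysms (MAs) in color fundus
    images. Implements a full lesion-detection pipeline: illumination
    normalisation and contrast enhancement of the fundus photograph,
    dual-gray-threshold morphological extraction of dark candidate
    regions with vessel suppression, a 40-dimensional feature bank per
    candidate (first-order salience statistics, gray-level co-occurrence
    texture features, and ring gradient descriptors that contrast a
    candidate's center against the darkest patch of its surrounding
    annulus), a gradient-boosted regression-tree classifier built on the
    logistic deviance, and candidate-level ROC plus lesion-level FROC
    evaluation. A seeded synthetic fundus generator with known lesion
    ground truth supports end-to-end testing without image downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    EBImage,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    xgboost,
    pROC,
    withr
biocViews: ImageProcessing, Classification
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
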