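Package: headmorph
Title: Personalized Head Finite-Element Models by Landmark Shape Regression and Thin-Plate-Spline Morphing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for building personalized human head finite-element (FE)
    models and studying vulnerable-road-user head injury. Implements a landmark
    statistical shape model (PCA of skull landmark configurations regressed on
    gender, age, height and BMI), thin-plate-spline radial-basis morphing of a
    baseline skull+brain FE mesh onto predicted landmark targets, mesh-quality
    (scaled Jacobian, equiangular skew) and geometric-error validation against
    target surfaces, a CORA-style corridor plus cross-correlation biofidelity
    rating for signal pairs, a five-degree brain von Mises injury classifier
    with dataset summaries, and a cross-validated prediction-evaluation harness
    (standardization, k-fold CV, grid search, classification and regression
    metrics) with pluggable estimators. Ships synthetic generators for landmark
    populations, baseline meshes, signal pairs and calibrated injury datasets
    so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    class
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
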