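Package: stridekit
Title: Stride-Length Estimation from Foot-Mounted Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates per-stride length from foot-mounted tri-axial
    accelerometer recordings. The pipeline combines db4 wavelet denoising
    and a five-point local cubic least-squares smoother with a three-state
    (displacement, velocity, acceleration) Kalman filter whose gain is
    transiently boosted at acceleration zero-crossings and whose
    displacement state carries a sign-consistency rule. A single-layer
    LSTM sequence regressor, trained on raw or filtered stride segments,
    provides a learning-based estimator, and a synthetic gait-signal
    generator with exactly known per-stride displacement makes every stage
    verifiable without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
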