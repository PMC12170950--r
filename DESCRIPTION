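Package: posturekit
Title: Marker- and Accelerometer-Based Quantification of Sitting Posture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement core for screening seated posture from a single
    sagittal-view camera and two wearable accelerometers. Detects square
    binary fiducial markers taped over the ear tragus, C7 spinous process
    and acromion, computes the craniovertebral and shoulder angles from
    their centroids, derives alpha/beta surface inclinations from 3-axis
    acceleration and composes them into a thoracic kyphosis angle,
    classifies forward head posture and hyperkyphosis against clinical
    thresholds, aggregates 1 Hz sessions into per-minute report statistics,
    and computes method-agreement measures (Pearson correlation with
    qualitative bands, MAPE). Includes a synthetic-fixture generator that
    renders marker frames at prescribed angular geometry and simulates
    accelerometer streams, reproducing the two-phase seated protocol used
    to validate the method.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
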