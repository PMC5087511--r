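Package: skelwatch
Title: Skeleton-Based Posture Recognition and Fall Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Vision-based telecare and telerehabilitation toolkit working on
    streams of 3D body-joint coordinates. Provides a from-scratch multilayer
    perceptron trained by full-batch backpropagation with a sum-form mean
    squared error objective, translation- and scale-invariant skeleton feature
    extraction, static posture classifiers for the upper and lower body, a
    sliding-window fall detector coupled to an escalating alarm state machine
    (Normal/Abnormal/Urgent/Emergency with a latching emergency stage), a
    rehabilitation session driver, a parametric synthetic skeleton and camera
    simulator that stands in for a depth sensor, and seeded evaluation sweeps
    over network size, training-set size, camera distance and camera angles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
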