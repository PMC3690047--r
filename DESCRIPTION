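Package: fruitglove
Title: Non-Destructive Fruit Grading from Glove-Style Pressure and Vision Sensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Software pipeline for grading climacteric fruit from wearable
    glove-style sensing: calibration of fingertip pressure transducers, force
    sensitive resistors, infrared distance sensors and finger-bend sensors
    (linear, polynomial, power-law and interpolating-spline transfer
    functions); laser-seeded interactive segmentation with fuzzy-connectedness
    region growing and optical-flow seed tracking; monocular and stereo
    pin-hole geometry for distance-invariant projected area, spherical radius
    and volume; RGB and near-infrared image fusion under a planar-object
    assumption; grasp-event detection on multi-finger pressure traces; and
    turgor-pressure-based ripeness classification with a weighted quality
    score. A synthetic scene and sensor simulator with machine-readable
    ground truth stands in for the physical hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
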