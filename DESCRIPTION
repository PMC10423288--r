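Package: pearlrot
Title: Non-Invasive Pearl Rotation Monitoring and Shape Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for magnetometer-based monitoring
    of cultured pearl rotation in Pinctada margaritifera. Models the dipole
    field of a magnetized nucleus inside a hemispherical dome of 25 single-axis
    magnetic sensors, reconstructs the magnet orientation trajectory from the
    raw channels, estimates rotation speed, renders trajectory images from a
    barycenter viewpoint, and classifies the final pearl shape (Round,
    Atypical, Other) with a frozen convolutional feature extractor fused with
    cultivation metadata, evaluated by grouped stratified repeated holdout.
    Includes a seeded synthetic-data generator (class-conditional rotation
    regimes, clock-driven calibration scenes, labeled cohorts) so the whole
    pipeline is testable without access to the original recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
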