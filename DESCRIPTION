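Package: pinholebp
Title: Calibration-Free Oscillometric Blood Pressure Estimation from
    Pinhole-Projection Camera Frames
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates and analyses fingertip oscillometry measured with a
    spring-loaded clip and a smartphone camera. A moveable pinhole projects a
    disc of light onto the camera sensor; the disc diameter encodes the force
    applied by the finger through a compression spring, and the disc
    brightness pulses with arterial blood volume (photoplethysmography). The
    package provides the spring/contact mechanics, a physics-based synthetic
    frame and cohort generator with known ground-truth blood pressure, the
    per-frame image features (histogram equalization, thresholded disc area,
    in-disc mean brightness), the guided 20-level force protocol state
    machine, oscillogram construction by band-pass filtering and
    peak-prominence pulse averaging, and a two-stage regression estimator
    (LASSO for systolic and mean pressure, linear for diastolic) validated by
    leave-two-subjects-out cross-validation with Bland-Altman agreement
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    png,
    withr,
    yaml
Config/testthat/edition: 3
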