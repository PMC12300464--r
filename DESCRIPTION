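Package: galvotherm
Title: Closed-Loop Galvanometric Laser Scanning Simulator for
    Photothermal Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A digital twin of a laser-scanning photothermal therapy
    (PTT) workstation. Models the geometry of a two-mirror galvanometric
    scanner (scan angles, command voltages, DAC codes), plans raster scan
    paths over a 30 x 30 treatment matrix, simulates an absorbing clay
    phantom with a 2-D explicit finite-difference heat model under
    scanned Gaussian laser heating, renders synthetic visible and thermal
    camera frames (keystone tilt, parallax offset, 8-bit thermal
    quantization), reconstructs thermograms and region-of-interest
    statistics through the segmentation / perspective-correction /
    parallax-alignment pipeline, and closes the loop with a discrete PID
    controller regulating laser power toward a mild-hyperthermia setpoint
    with a hard safety cap. Every stage is exercised against the
    simulated phantom so the whole feedback loop is testable without
    hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
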