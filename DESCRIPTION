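Package: gazemaze
Title: Gaze-Controlled Maze Therapy Monitoring and Session Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hardware-free toolkit for landmark-based eye tracking and
    oculomotor therapy monitoring in amblyopia management. Converts streams
    of iris and eye-contour landmarks into normalized lateral and
    anteroposterior gaze ratios via a minimum enclosing circle pupil
    estimate, maps gaze to five-zone joystick commands with adaptive
    calibrated thresholds, simulates a five-level maze therapy game with
    collision and checkpoint timing, and computes the full session
    analytics stack: displacement extremes, ellipse graphs, performance
    ratios, segment statistics, weekly linear regressions, fixation
    validation tables, two-way ANOVA, and System Usability Scale scoring.
    Includes a seeded synthetic landmark-stream generator so every
    component is testable without a camera or sensor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    tibble,
    ggplot2,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
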