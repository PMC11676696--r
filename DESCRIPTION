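Package: tricadence
Title: Cadence and Cycling-Task Analysis from a Single Trunk-Mounted IMU
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing triathlon performance from a single
    trunk-mounted inertial measurement unit (100 Hz tri-axial accelerometer
    and gyroscope, optional 10 Hz GPS). Provides band-pass peak counting of
    swimming strokes, cycling pedal strokes and running strides over
    customisable epochs; short-time Fourier transform window features and a
    gradient-boosted classifier that recognises in-saddle versus
    out-of-saddle riding with a participant-level hold-out protocol;
    count-level and window-level evaluation metrics; GeoJSON map exports of
    task classification and rolling cadence along the GPS track; and a
    seeded synthetic IMU session generator with exact ground truth for
    validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    xgboost,
    yaml
Suggests:
    geosphere,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
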