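Package: spo2cam
Title: Contactless SpO2 Estimation from Face Video by Remote Photoplethysmography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates peripheral oxygen saturation (SpO2) from ordinary
    camera video of a face using the ratio-of-ratios principle of remote
    photoplethysmography (rPPG). Provides forehead region-of-interest
    extraction of red and blue channel time series, cardiac-band Butterworth
    filtering, windowed AC/DC statistics, linear calibration of the
    ratio-of-ratios to SpO2, triage classification, and agreement metrics
    (mean absolute error) against reference pulse-oximeter readings. A
    minimal histogram-of-oriented-gradients descriptor is included as the
    feature primitive behind landmark-based face detection, and a synthetic
    pulsatile-scene generator makes every pipeline stage testable without a
    camera or a subject.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
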