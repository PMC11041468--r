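Package: spo2cdss
Title: Component-Based Artifact Detection and SpO2 Alarm Generation for
    Vital-Sign Monitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for composing clinical decision support pipelines that
    suppress false pulse-oximetry alarms in neonatal intensive care. Provides
    a common reference model for signal-quality-annotated vital-sign numeric
    streams (SpO2, heart rate, pulse rate, alarm status), four artifact
    detection operators (symbol de-interlacing, signal-quality fusion,
    dual-sensor differencing, quality-masked median filtering), an
    integrated-error SpO2 alarm generator with annunciation delays, four
    preset pipeline compositions, sensitivity / false-alarm-rate evaluation
    with leave-one-out cross-validation, and a seeded synthetic neonatal
    monitor simulator with ground-truth desaturation events.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
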