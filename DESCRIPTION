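Package: ambecg
Title: Murine Ambulatory ECG Processing, R-Peak Detection and Heart-Rate
    Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for long-term ambulatory electrocardiography (AECG) in
    mice: reading and writing multi-lead recordings, Einthoven and
    Goldberger lead algebra, a zero-phase pre-processing chain (Butterworth
    high-pass, decimation, FFT band-pass, zero-phase derivative), R-peak
    detection with height and refractory-distance thresholds, heart rate,
    RR-interval and histogram full-width-at-half-maximum (FWHM) heart-rate
    variability extraction, semi-automatic ectopic-beat flagging from
    RR-interval deviation against a moving average with region-of-interest
    export for manual review, and detector evaluation against reference
    annotations (sensitivity, precision, specificity, paired detector
    comparison). Includes a synthetic murine ECG simulator with exact
    ground truth so every stage is testable without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
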