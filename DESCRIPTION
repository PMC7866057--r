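Package: tugkit
Title: Timed Up and Go Test Analysis from UWB Radar and Instrumented Insole Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated analysis of the Timed Up and Go (TUG) clinical mobility
    test from two unobtrusive sensor streams: an ultra-wideband radar range
    trace and an instrumented-insole recording (anteroposterior acceleration
    plus force-sensitive-resistor channels). Provides constant-acceleration
    Kalman filtering of radar range for velocity estimation, rule-based
    segmentation of the trial into sit-to-stand, walk-forward, turn, walk-back
    and stand-to-sit phases, zero-crossing/locking-period stride detection
    with peak correction from insole acceleration, force-based validation and
    sit-stand transition detection, three calibrated acceleration-based
    stride-length estimators, a 0-100 risk-of-falling (ROFA) gait-deviation
    score with risk bands, paired Wilcoxon/RMSE comparison of radar and insole
    stride lengths, and a synthetic TUG-trial simulator with ground truth for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
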