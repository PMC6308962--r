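Package: tracheidnir
Title: Lifting-Wavelet De-Noising and PLS Calibration of Wood Tracheid
    Length from Vis-NIR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Signal-processing toolkit for ring-resolved visible/near-
    infrared prediction of wood tracheid length: lifting-scheme wavelet
    transform with global fixed hard-threshold de-noising, the local
    correlation maximization hybrid-spectrum algorithm, classical
    smoothing comparators (moving average, Savitzky-Golay, loess,
    lowess), NIPALS partial least squares calibration with standard
    chemometric diagnostics, and a synthetic ring-resolved cohort
    generator for end-to-end testing of the de-noising parameter
    selection workflow.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
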