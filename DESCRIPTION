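Package: wavehr
Title: Continuous Heart-Rate Estimation from ECG and PPG via Wavelet
    Oscillatory Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates a continuous, equidistant instantaneous heart-rate
    series from single-channel ECG or photoplethysmogram (PPG) recordings by
    tracking ridges ("oscillatory patterns") on the Morlet continuous
    wavelet transform energy surface. Skeleton curves (per-time local maxima
    of the scalogram) are linked across time by an epsilon-neighbourhood
    rule and the dominant pattern inside the fundamental cardiac band, with
    a second-harmonic consistency check, yields heart rate at one tenth of
    the signal sampling rate. Includes a classical R-peak contour baseline,
    Bland-Altman agreement statistics, LF/HF spectral indices of heart-rate
    variability, readers for WFDB/EDF/CSV physiological recordings, and a
    seeded synthetic ECG/PPG generator with known ground-truth rate for
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
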