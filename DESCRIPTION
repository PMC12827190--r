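Package: mecg
Title: Cardiac Signal Extraction and Heart Rate Variability from MEG Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts MEG-derived electrocardiogram (M-ECG) traces from
    multichannel magnetoencephalography recordings, either as a cardiac
    independent component (FastICA) or from reference sensors, detects
    R-peaks with a two-stage adaptive amplitude threshold, corrects
    aberrant RR intervals by statistical flagging and interpolation, and
    computes time- and frequency-domain heart rate variability indices.
    Includes agreement statistics (peak pairing, detection benchmarking,
    Bland-Altman, Lin's concordance, dynamic time warping) against an
    independently recorded ECG, and a seeded synthetic generator that
    produces ECG-like traces with known R-peak times mixed into noisy
    sensor arrays for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
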