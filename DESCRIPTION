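Package: bioqc
Title: Quality Assessment of Multimodal Biopotential Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
                  role = c("aut", "cre"))
Description: Tools for quantitative quality assessment of ECG, EMG and EEG
    recordings sampled as plain-text time series. Implements the classical
    ECG signal-quality indices (kurtosis kSQI, QRS-band relative power pSQI,
    baseline relative power basSQI), a fuzzy comprehensive evaluation that
    aggregates them into a quality score and grade with a three-route
    decision workflow, heart-rate-variability time- and frequency-domain
    analysis from detected R peaks, EEG alpha-band (8-13 Hz) spectral
    analysis with eyes-open/eyes-closed detection, and channel-comparison
    metrics (RMS signal-to-noise ratio and normalized cross-correlation).
    A synthetic generator produces ECG, EMG and EEG records with known
    ground truth (R-peak times, burst epochs, noise traces) for validation.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
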