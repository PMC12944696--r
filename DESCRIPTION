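Package: ecgfuse
Title: Motion-Robust Arrhythmia Screening by Attention-Gated ECG and
    Accelerometer Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for motion-robust arrhythmia screening from single-lead
    wearable ECG with a synchronized tri-axial accelerometer.  Implements the
    full pipeline: WFDB-dialect record reading and AAMI-style beat labelling,
    Butterworth band-pass conditioning and windowed z-normalization, log-power
    spectrograms, Pan-Tompkins QRS detection with adaptive thresholds and
    heart-rate-variability statistics, accelerometer motion features and
    motion-intensity classes, SNR-calibrated electrode-motion noise
    augmentation with SNR-coupled synthetic accelerometer traces, a dual-stream
    neural classifier (residual spectrogram encoder plus CNN-BiLSTM motion
    encoder) joined by attention-gated fusion with gate-diversity
    regularization, paired-classifier evaluation statistics, and a
    hierarchical two-stage screening layer with an expected-latency model and
    a three-tier alarm policy.  A synthetic-fixtures generator provides
    parametric ECG beats, electrode-motion artifact noise and
    activity-dependent accelerometer traces so the whole pipeline is testable
    without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
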