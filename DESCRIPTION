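Package: stseize
Title: Seizure Detection from Scalp EEG via Stockwell Transform and a
    Transformer Encoder
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automatic epileptic seizure detection for long-term
    multichannel scalp EEG. Four-second epochs are mapped to
    time-frequency representations with the Stockwell transform (with a
    brute-force direct oracle and an FFT-accelerated implementation),
    compressed into per-channel rhythm sub-band energy features (delta
    through gamma, two time blocks), and classified by a small
    Transformer encoder that treats each EEG channel as a token
    (channel embedding, no positional encoding) and exposes per-channel
    attention weights. The per-epoch probability stream is turned into
    event decisions with moving-average filtering, thresholding, a
    collar, and K-of-N discrimination, and scored with segment-based
    (accuracy, sensitivity, specificity, precision, AUC) and
    event-based (sensitivity, false detections per hour, detection
    latency) metrics. A seeded synthetic EEG generator emulating
    CHB-MIT-style recordings makes the full pipeline testable without
    external data; EDF and CSV readers and writers connect it to real
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
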