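Package: somnoloop
Title: Wearable Sleep Staging and Closed-Loop Acoustic Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Real-time four-stage sleep scoring from multimodal wearable
    recordings (six-channel ExG, photoplethysmography, 3-axis accelerometry)
    with per-epoch channel-quality assessment, dynamic re-referencing, a
    primary ExG classifier, a secondary vitals classifier, and offline
    hypnogram smoothing by maximum-likelihood path decoding. Includes a
    closed-loop acoustic-stimulation controller built on a real-time
    probability-of-being-asleep trace, sleep-onset detection, automatic
    content switching, and Thompson-sampling audio-content recommendation,
    plus a synthetic polysomnography simulator that generates stage-dependent
    electrophysiology, vitals, posture, and contact-loss artifacts for fully
    reproducible benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
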