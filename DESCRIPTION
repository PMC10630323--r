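Package: ppgvitals
Title: Vitals Estimation and Single-Lead ECG Synthesis from Smartphone
    Photoplethysmography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for turning fingertip-video photoplethysmography (PPG)
    into cardiorespiratory vitals and a synthetic single-lead ECG. Covers
    the full pipeline: pixel-averaged PPG extraction from frame stacks,
    wavelet denoising and envelope detrending, TERMA peak detection,
    sliding-window segmentation, compact neural regressors for heart rate,
    blood oxygen saturation and respiratory rate (including a contrastive
    PPG-caption retrieval model), and cycle-wise PPG-to-ECG translation by
    truncated discrete cosine transform regression in ridge and
    feed-forward configurations. A seeded synthetic paired-signal
    generator provides ground-truthed fixtures for training and
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
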