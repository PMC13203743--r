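Package: mieeg
Title: Multi-View Fusion of Time-Frequency and Raw-Signal Representations
    for Few-Channel Motor-Imagery EEG Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete classification pipeline for few-channel (C3/Cz/C4)
    motor-imagery EEG. Trials are bandpass filtered, sliced into 0.5 s
    segments, and converted per channel into complex-Morlet continuous
    wavelet transform scalograms stacked like an RGB image; a parallel raw
    time-domain view is dimension-aligned and fused with the scalogram view
    through independent 1x1 convolutions. The fused slice sequence is
    encoded by a compact channel-shuffle convolutional backbone and modeled
    temporally by a Transformer encoder, trained end-to-end with
    cross-entropy. Includes a statistically structured synthetic MI-EEG
    generator (lateralized mu/beta event-related desynchronization over
    pink noise), a reader for GDF motor-imagery recordings, and an ablation
    harness over fusion views, backbones, and temporal models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    signal,
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
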