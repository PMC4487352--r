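Package: isocall
Title: Detection, Segmentation and Acoustic Analysis of Kitten Isolation Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated pipeline for the analysis of kitten vocalizations from
    long session recordings: adaptive RMS-threshold call detection after
    Butterworth high-pass filtering, frame-wise voiced/unvoiced classification by
    normalized autocorrelation with simple inverse filter tracking (SIFT)
    correction, constrained autocorrelation F0 (pitch) tracking, first-harmonic
    (F1) tracking and F1/F0 harmonic-ratio statistics, onset-aligned average
    spectrograms and Welch power spectra, and a developmental group-comparison
    statistical battery (normality, variance and mean tests across age bins and
    hearing-status groups). Includes a synthetic vocalization simulator that
    generates sessions of harmonic isolation calls, purr-like unvoiced calls,
    combined calls and nonlinear phenomena (subharmonics, frequency jumps,
    biphonation) with ground-truth annotations, so every pipeline stage is
    testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nortest,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
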