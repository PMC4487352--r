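# Shared fixtures: all synthetic, built in code at test time.

FS <- 44100

# Full single-call analysis chain: frames -> F0 track -> F1 track -> features.
analyzeCallWave <- function(w, fs = FS, expectedF0MaxHz = 1000, sift = TRUE) {
  fr <- segmentFrames(w, fs, sift = sift)
  tr <- estimateF0Track(w, fr, fs, expectedF0MaxHz)
  tr <- estimateF1Track(w, tr, fs)
  computeCallFeatures(w, tr, fs)
}

makeTone <- function(freqHz, durationS, fs = FS, amp = 0.5) {
  amp * sin(2 * pi * freqHz * (seq_len(round(durationS * fs)) - 0.5) / fs)
}

# Frequencies of local maxima of a power spectrum above a relative floor.
spectralPeaks <- function(spec, relFloor = 1e-3) {
  p <- spec$power
  isPeak <- c(FALSE, p[2:(length(p) - 1)] > p[1:(length(p) - 2)] &
                p[2:(length(p) - 1)] >= p[3:length(p)], FALSE)
  spec$freq_hz[isPeak & p > relFloor * max(p)]
}
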