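# Argmax with plateau-aware tie-breaking: the median filter turns an isolated
# peak into a short run of tied maxima; the center of the maximal run is the
# position of the underlying energy maximum.
.argmaxCenter <- function(v) {
  idx <- which(v == max(v))
  idx[ceiling(length(idx) / 2)]
}

# Frame a signal into columns: starts every `hop`, length `win`.
# Frame count = 1 + floor((n - win) / hop).
.frameMatrix <- function(x, win, hop) {
  n <- length(x)
  if (n < win) stop("signal shorter than the analysis window", call. = FALSE)
  starts <- seq(1L, n - win + 1L, by = hop)
  matrix(x[outer(0:(win - 1L), starts, "+")], nrow = win)
}

# One-sided power spectra of windowed frames (columns), zero-padded to nfft.
.framePower <- function(frames, window, nfft) {
  fw <- frames * window
  if (nfft > nrow(fw))
    fw <- rbind(fw, matrix(0, nfft - nrow(fw), ncol(fw)))
  X <- mvfft(fw)
  (Mod(X)^2)[seq_len(nfft / 2 + 1), , drop = FALSE]
}

#' Short-time Fourier spectrogram of a call
#'
#' Magnitude-squared STFT with a Hamming window (default length 1024 samples,
#' 75 \% overlap). Frame count is \code{1 + floor((N - win)/hop)} with
#' \code{hop = win * (1 - overlap)}.
#'
#' @param x numeric call waveform.
#' @param fs sampling rate (Hz).
#' @param win window / FFT length in samples (default 1024).
#' @param overlap fractional overlap between windows (default 0.75).
#' @return a \linkS4class{Spectrogram} (linear power; rows = frequency bins,
#'   columns = frames; times at frame centers).
#' @export
stftSpectrogram <- function(x, fs, win = 1024, overlap = 0.75) {
  hop <- round(win * (1 - overlap))
  stopifnot(hop >= 1)
  frames <- .frameMatrix(x, win, hop)
  w <- signal::hamming(win)
  P <- .framePower(frames, w, win)
  starts <- seq(1L, length(x) - win + 1L, by = hop)
  new("Spectrogram", power = P,
      timesS = (starts - 1L + win / 2) / fs,
      freqsHz = (0:(win / 2)) * fs / win,
      params = list(win = win, hop = hop, nfft = win, overlap = overlap,
                    fs = fs, window = "hamming"))
}

#' Onset-aligned average spectrogram over calls
#'
#' Each call's spectrogram is normalized to its own maximum power, all calls
#' are left-aligned at onset, and the normalized spectrograms are averaged
#' frame-by-frame out to the longest call. At frame indices beyond the end of
#' a shorter call, that call simply does not contribute (the denominator of
#' the average varies with frame index); this avoids the low-bias that
#' zero-padding shorter calls would introduce. Onset alignment makes the
#' changing frequency components at the start of vocalization visible in the
#' average -- e.g. the juvenile onset FM sweep.
#'
#' @param calls list of numeric call waveforms (or
#'   \linkS4class{Spectrogram}s), each one eligible per
#'   [spectrogramEligibility()].
#' @param fs sampling rate (Hz), used when waveforms are given.
#' @param win,overlap STFT parameters (see [stftSpectrogram()]).
#' @return a \linkS4class{Spectrogram}; maximum value at most 1.
#' @export
averageSpectrogram <- function(calls, fs, win = 1024, overlap = 0.75) {
  if (length(calls) == 0) stop("no calls to average", call. = FALSE)
  specs <- lapply(calls, function(cl) {
    if (is(cl, "Spectrogram")) cl else stftSpectrogram(cl, fs, win, overlap)
  })
  nFrames <- vapply(specs, function(s) ncol(s@power), integer(1))
  nb <- nrow(specs[[1]]@power)
  acc <- matrix(0, nb, max(nFrames))
  cnt <- numeric(max(nFrames))
  for (s in specs) {
    P <- s@power / max(s@power)
    k <- ncol(P)
    acc[, seq_len(k)] <- acc[, seq_len(k)] + P
    cnt[seq_len(k)] <- cnt[seq_len(k)] + 1
  }
  avg <- sweep(acc, 2, cnt, "/")
  ref <- specs[[1]]
  new("Spectrogram", power = avg,
      timesS = (seq_len(ncol(avg)) - 1) * ref@params$hop / ref@params$fs +
        ref@params$win / 2 / ref@params$fs,
      freqsHz = ref@freqsHz,
      params = c(ref@params, list(nCalls = length(specs))))
}

#' Welch power spectrum of a call, normalized to maximum
#'
#' Averaged modified periodogram (Hamming window, default FFT length 1024,
#' 50 \% overlap between segments), normalized so the maximum power is 1.
#'
#' @param x numeric call waveform.
#' @param fs sampling rate (Hz).
#' @param nfft segment / FFT length (default 1024).
#' @param overlap fractional overlap between Welch segments (default 0.5).
#' @return data.frame: \code{freq_hz}, \code{power} (max = 1).
#' @export
welchSpectrum <- function(x, fs, nfft = 1024, overlap = 0.5) {
  hop <- round(nfft * (1 - overlap))
  frames <- .frameMatrix(x, nfft, hop)
  w <- signal::hamming(nfft)
  P <- rowMeans(.framePower(frames, w, nfft))
  data.frame(freq_hz = (0:(nfft / 2)) * fs / nfft, power = P / max(P))
}

#' Average normalized Welch spectra over a set of calls
#'
#' Per-call spectra are first normalized to their own maximum
#' ([welchSpectrum()]) and then averaged -- normalization precedes averaging.
#'
#' @param calls list of numeric call waveforms.
#' @inheritParams welchSpectrum
#' @return data.frame: \code{freq_hz}, \code{power}.
#' @export
averageWelchSpectra <- function(calls, fs, nfft = 1024, overlap = 0.5) {
  if (length(calls) == 0) stop("no calls to average", call. = FALSE)
  specs <- lapply(calls, welchSpectrum, fs = fs, nfft = nfft,
                  overlap = overlap)
  data.frame(freq_hz = specs[[1]]$freq_hz,
             power = rowMeans(vapply(specs, `[[`, numeric(nrow(specs[[1]])),
                                     "power")))
}

#' Time-frequency representation for F0/F1 tracking
#'
#' Short-window FFT analysis (10-ms sliding window, 50 \% overlap, zero-padded
#' to \code{nfft}) followed by a 5-point median filter along frequency within
#' each frame. For well-formed harmonic frames the median filter does not move
#' the position of the energy maxima: the filter flattens an isolated peak
#' into a short run of tied maxima whose center is the original peak, so
#' dominant-bin positions are computed with plateau-center tie-breaking. The
#' number of frames whose dominant (above-500-Hz) bin moved is recorded in
#' \code{params$argmaxShifted} so the invariance can be checked; the
#' unsmoothed power is kept in \code{params$rawPower} for sub-bin peak
#' refinement.
#'
#' @param x numeric call waveform.
#' @param fs sampling rate (Hz).
#' @param winMs analysis window in milliseconds (default 10; 5 ms with high
#'   overlap is a visual-control preset).
#' @param overlap fractional overlap (default 0.5).
#' @param nfft FFT length after zero-padding (default 1024).
#' @param medianK median filter length in bins (default 5).
#' @return a \linkS4class{Spectrogram} of the smoothed power;
#'   \code{params$rawArgmax} / \code{params$smoothArgmax} hold the per-frame
#'   dominant-bin indices before/after smoothing, \code{params$argmaxShifted}
#'   the count of frames where they differ.
#' @export
tfForTracking <- function(x, fs, winMs = 10, overlap = 0.5, nfft = 1024,
                          medianK = 5) {
  win <- round(winMs / 1000 * fs)
  hop <- max(1L, round(win * (1 - overlap)))
  frames <- .frameMatrix(x, win, hop)
  w <- signal::hamming(win)
  nfft <- max(nfft, 2^ceiling(log2(win)))
  P <- .framePower(frames, w, nfft)
  S <- apply(P, 2, function(col) stats::runmed(col, medianK))
  freqs <- (0:(nfft / 2)) * fs / nfft
  band <- freqs >= 500          # analysis band starts above the high-pass
  rawArg <- apply(P[band, , drop = FALSE], 2, .argmaxCenter)
  # the filter flattens a peak into a run of tied maxima: the position is
  # unchanged iff the raw peak lies within that run
  Sb <- S[band, , drop = FALSE]
  smoArg <- vapply(seq_len(ncol(Sb)), function(j) {
    idx <- which(Sb[, j] == max(Sb[, j]))
    idx[which.min(abs(idx - rawArg[j]))]
  }, integer(1))
  starts <- seq(1L, length(x) - win + 1L, by = hop)
  new("Spectrogram", power = S,
      timesS = (starts - 1L + win / 2) / fs,
      freqsHz = freqs,
      params = list(win = win, hop = hop, nfft = nfft, overlap = overlap,
                    fs = fs, window = "hamming", medianK = medianK,
                    rawPower = P,
                    rawArgmax = rawArg, smoothArgmax = smoArg,
                    argmaxShifted = sum(rawArg != smoArg)))
}
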