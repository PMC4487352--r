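# FFT-based autocorrelation of a frame, lags 0..maxLag (unnormalized).
.autocorr <- function(x, maxLag) {
  n <- length(x)
  nfft <- 2^ceiling(log2(2 * n))
  X <- fft(c(x, numeric(nfft - n)))
  r <- Re(fft(X * Conj(X), inverse = TRUE)) / nfft
  r[seq_len(min(maxLag, n - 1) + 1)]
}

# Lag search range (samples) for a pitch band in Hz.
.lagRange <- function(fs, bandHz, frameLen) {
  lo <- max(2L, floor(fs / bandHz[2]))
  hi <- min(frameLen - 1L, ceiling(fs / bandHz[1]))
  if (lo > hi) stop("pitch lag range empty for this frame length",
                    call. = FALSE)
  c(lo, hi)
}

#' Voicing decision for one 10-ms frame
#'
#' A frame is voiced when the normalized autocorrelation peak -- the maximum
#' of the autocorrelation over positive lags in the pitch search range,
#' divided by the lag-0 value -- exceeds the threshold (default 0.6).
#' Quasi-periodic (glottal) excitation produces a strong peak at the pitch
#' period; aperiodic noise does not. A zero-energy frame is unvoiced with
#' ratio 0.
#'
#' @param frame numeric samples of one analysis frame (nominally
#'   \code{round(0.010 * fs)} samples).
#' @param fs sampling rate (Hz).
#' @param pitchBandHz lag search range expressed in Hz (default 400-2000 Hz,
#'   covering kitten F0 near 1 kHz with slack).
#' @param thresh voicing threshold on the normalized peak (default 0.6).
#' @return list: \code{voiced}, \code{acPeakRatio}, \code{bestLagS}.
#' @export
frameVoicing <- function(frame, fs, pitchBandHz = c(400, 2000), thresh = 0.6) {
  n <- length(frame)
  lr <- .lagRange(fs, pitchBandHz, n)
  r <- .autocorr(frame, lr[2])
  if (r[1] <= 0)
    return(list(voiced = FALSE, acPeakRatio = 0, bestLagS = NA_real_))
  lags <- lr[1]:lr[2]
  rl <- r[lags + 1] / r[1]
  i <- which.max(rl)
  list(voiced = rl[i] > thresh, acPeakRatio = rl[i],
       bestLagS = lags[i] / fs)
}

# LPC coefficients (autocorrelation method / Levinson-Durbin), a[1] = 1.
.lpc <- function(x, p) {
  r <- .autocorr(x, p)
  if (r[1] <= 0) return(NULL)
  a <- 1; e <- r[1]
  for (i in seq_len(p)) {
    k <- -(sum(a * r[i:1 + 1])) / e
    if (!is.finite(k)) return(NULL)
    a <- c(a, 0) + k * c(0, rev(a))
    e <- e * (1 - k^2)
    if (e <= 0) break
  }
  a
}

#' SIFT correction of frame voicing over one segment
#'
#' Simple inverse filter tracking: each frame is whitened by its own
#' linear-prediction inverse filter (order \code{lpcOrder}, default 12), the
#' voicing ratio is re-scored on the autocorrelation of the residual, and a
#' continuity rule then flips isolated single-frame disagreements with both
#' neighbours. Whitening removes the spectral envelope so the periodicity
#' decision rests on the excitation alone. If the re-scoring disagrees with
#' the incoming flags on more than half the frames it is considered
#' unreliable and the incoming flags are kept (bounded intervention); the
#' continuity rule still applies.
#'
#' @param frames data.frame of frame analyses (from [segmentFrames()]):
#'   columns \code{voiced}, \code{ac_peak_ratio} at minimum.
#' @param segSignal numeric samples of the whole segment the frames tile.
#' @param fs sampling rate (Hz).
#' @param lpcOrder LPC order (default 12).
#' @param pitchBandHz pitch search band (Hz).
#' @param thresh voicing threshold (default 0.6).
#' @param mode \code{"rescore"} (default: inverse-filter re-scoring plus
#'   continuity) or \code{"smooth"} (continuity rule only).
#' @return the frames data.frame with corrected \code{voiced} flags.
#' @export
siftCorrect <- function(frames, segSignal, fs, lpcOrder = 12,
                        pitchBandHz = c(400, 2000), thresh = 0.6,
                        mode = c("rescore", "smooth")) {
  mode <- match.arg(mode)
  nf <- nrow(frames)
  frameLen <- round(0.010 * fs)
  if (nf * frameLen > length(segSignal) + frameLen)
    stop("frames and segment signal are misaligned", call. = FALSE)
  flags <- frames$voiced
  if (mode == "rescore" && nf > 0) {
    rescored <- logical(nf)
    for (i in seq_len(nf)) {
      idx <- ((i - 1) * frameLen + 1):min(i * frameLen, length(segSignal))
      x <- segSignal[idx]
      a <- if (sum(x^2) > 0) .lpc(x, lpcOrder) else NULL
      if (is.null(a)) { rescored[i] <- FALSE; next }
      e <- as.numeric(stats::filter(x, a, method = "convolution", sides = 1))
      e <- e[!is.na(e)]
      fv <- frameVoicing(e, fs, pitchBandHz, thresh)
      rescored[i] <- fv$voiced
    }
    if (sum(rescored != flags) <= ceiling(nf / 2)) flags <- rescored
  }
  if (nf >= 3) {
    prev <- flags[1:(nf - 2)]; nxt <- flags[3:nf]; cur <- flags[2:(nf - 1)]
    iso <- which(cur != prev & prev == nxt)
    flags[iso + 1] <- prev[iso]
  }
  frames$voiced <- flags
  frames
}

#' Frame-wise voicing analysis of one detected segment
#'
#' Tiles the segment into non-overlapping 10-ms frames, applies
#' [frameVoicing()] to each, and (optionally) the [siftCorrect()] correction.
#'
#' @param segSignal numeric samples of the segment.
#' @param fs sampling rate (Hz).
#' @param sift apply SIFT correction (default TRUE).
#' @param ... passed on to [frameVoicing()] / [siftCorrect()].
#' @return data.frame: \code{frame_index} (0-based), \code{t_center_s}
#'   (seconds from segment onset), \code{ac_peak_ratio}, \code{best_lag_s},
#'   \code{voiced}.
#' @export
segmentFrames <- function(segSignal, fs, sift = TRUE, ...) {
  frameLen <- round(0.010 * fs)
  nf <- floor(length(segSignal) / frameLen)
  if (nf < 1) stop("segment shorter than one 10-ms frame", call. = FALSE)
  rows <- lapply(seq_len(nf), function(i) {
    x <- segSignal[((i - 1) * frameLen + 1):(i * frameLen)]
    fv <- frameVoicing(x, fs, ...)
    data.frame(frame_index = i - 1L,
               t_center_s = ((i - 1) + 0.5) * frameLen / fs,
               ac_peak_ratio = fv$acPeakRatio,
               best_lag_s = fv$bestLagS,
               voiced = fv$voiced)
  })
  frames <- do.call(rbind, rows)
  if (sift) frames <- siftCorrect(frames, segSignal, fs)
  frames
}

#' Classify a whole call from its frame voicing flags
#'
#' \describe{
#'   \item{voiced}{at least \code{voicedFrac} of frames voiced and no leading
#'     unvoiced run of \code{leadMs} or more.}
#'   \item{combined}{a leading unvoiced run of at least \code{leadMs}
#'     followed by a voiced run of at least 100 ms (the unvoiced-onset,
#'     voiced-continuation structure).}
#'   \item{unvoiced}{otherwise.}
#' }
#'
#' @param voicedFlags logical vector, one flag per 10-ms frame.
#' @param frameDt frame duration in seconds (default 0.010).
#' @param voicedFrac minimum voiced-frame fraction for a voiced call
#'   (default 0.5).
#' @param leadMs minimum leading unvoiced run for a combined call, in ms
#'   (default 100).
#' @return one of \code{"voiced"}, \code{"unvoiced"}, \code{"combined"}.
#' @export
classifyCall <- function(voicedFlags, frameDt = 0.010, voicedFrac = 0.5,
                         leadMs = 100) {
  if (length(voicedFlags) == 0) stop("empty frame list", call. = FALSE)
  leadFrames <- ceiling(leadMs / 1000 / frameDt)
  minVoicedRun <- ceiling(0.100 / frameDt)
  r <- rle(voicedFlags)
  lead <- if (!r$values[1]) r$lengths[1] else 0L
  if (lead >= leadFrames) {
    later <- r$lengths[-1][r$values[-1]]
    if (length(later) && max(later) >= minVoicedRun) return("combined")
    return("unvoiced")
  }
  if (mean(voicedFlags) >= voicedFrac) "voiced" else "unvoiced"
}
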