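# Parabolic interpolation of a discrete peak: offset in [-0.5, 0.5] from i.
.parabolicOffset <- function(ym1, y0, yp1) {
  den <- ym1 - 2 * y0 + yp1
  if (!is.finite(den) || den >= 0) return(0)
  off <- 0.5 * (ym1 - yp1) / den
  max(-0.5, min(0.5, off))
}

#' Estimate the F0 track of a voiced call
#'
#' Per voiced 10-ms frame, the fundamental is \code{fs / lag} at the best
#' autocorrelation lag, searched only over lags whose frequencies lie within
#' \code{[0.7, 1.3] * expectedF0MaxHz} (the +/-30 \% constraint that prevents
#' octave confusion with the first harmonic). The peak lag is refined by
#' parabolic interpolation of the autocorrelation. Frames whose constrained
#' peak ratio falls below \code{ratioFloor}, or whose peak is pinned to a
#' search-band edge with a clipped interpolation offset (the true period
#' lies outside the band), are marked invalid -- the automatic counterpart
#' of manually discarding contaminated F0 frames.
#'
#' @param segSignal numeric samples of the whole segment.
#' @param frames frame analysis from [segmentFrames()] (voicing flags).
#' @param fs sampling rate (Hz).
#' @param expectedF0MaxHz expected maximum F0 (default 1000 Hz -- kitten
#'   isolation calls sit near 1 kHz); configurable per session.
#' @param ratioFloor validity floor on the constrained normalized
#'   autocorrelation peak (default 0.3).
#' @return a \linkS4class{ContourTrack} (F0 only; NA at unvoiced/invalid
#'   frames).
#' @export
estimateF0Track <- function(segSignal, frames, fs, expectedF0MaxHz = 1000,
                            ratioFloor = 0.3) {
  if (!any(frames$voiced)) stop("no voiced frames in segment", call. = FALSE)
  frameLen <- round(0.010 * fs)
  band <- c(0.7, 1.3) * expectedF0MaxHz
  lagLo <- max(2L, floor(fs / band[2]))
  lagHi <- min(frameLen - 2L, ceiling(fs / band[1]))
  if (lagLo >= lagHi)
    stop("F0 search band empty at this sampling rate", call. = FALSE)
  nf <- nrow(frames)
  f0 <- rep(NA_real_, nf)
  valid <- rep(FALSE, nf)
  for (i in seq_len(nf)) {
    if (!frames$voiced[i]) next
    idx <- ((i - 1) * frameLen + 1):min(i * frameLen, length(segSignal))
    x <- segSignal[idx]
    r <- .autocorr(x, lagHi + 1L)
    if (r[1] <= 0) next
    lags <- lagLo:lagHi
    rl <- r[lags + 1]
    j <- which.max(rl)
    if (rl[j] / r[1] < ratioFloor) next
    lag <- lags[j]
    off <- .parabolicOffset(r[lag], r[lag + 1], r[lag + 2])
    # peak pinned to the search-band edge with a clipped interpolation
    # offset: the true period lies outside the band and the estimate would
    # be contaminated -- mark the frame invalid instead
    if ((j == 1 && off <= -0.499) || (j == length(lags) && off >= 0.499))
      next
    f0[i] <- fs / (lag + off)
    valid[i] <- TRUE
  }
  ContourTrack(frames$t_center_s, f0, valid = valid)
}

#' Estimate the F1 (first-harmonic) track of a call
#'
#' Per frame with a valid F0, F1 is the frequency of the maximum of the
#' median-smoothed time-frequency power within \code{[1.5, 2.5] * F0}, refined
#' by parabolic interpolation over frequency bins. Searching near (rather than
#' fixing) 2 x F0 lets the harmonic ratio F1/F0 deviate from 2, which is
#' exactly the informative case. Frames with invalid F0 stay invalid.
#'
#' @param segSignal numeric samples of the segment.
#' @param f0Track \linkS4class{ContourTrack} from [estimateF0Track()].
#' @param fs sampling rate (Hz).
#' @param tf optional precomputed [tfForTracking()] spectrogram of the
#'   segment.
#' @return the track with \code{f1Hz} filled.
#' @export
estimateF1Track <- function(segSignal, f0Track, fs, tf = NULL) {
  if (is.null(tf)) tf <- tfForTracking(segSignal, fs)
  P <- tf@power
  R <- tf@params$rawPower
  freqs <- tf@freqsHz
  dF <- freqs[2] - freqs[1]
  nf <- length(f0Track@timesS)
  f1 <- rep(NA_real_, nf)
  valid <- f0Track@valid
  # F1 at one spectrogram frame: locate on the smoothed power
  # (plateau-center), refine on the raw spectrum via the nearest raw local
  # maximum and log-power parabolic interpolation for sub-bin resolution.
  f1At <- function(j, f0) {
    binLo <- which(freqs >= 1.5 * f0)[1]
    binHi <- max(which(freqs <= 2.5 * f0))
    if (is.na(binLo) || binHi <= binLo)
      stop("F1 search band empty (aliasing edge)", call. = FALSE)
    k <- binLo - 1L + .argmaxCenter(P[binLo:binHi, j])
    raw <- R[, j]
    lo <- max(binLo, k - 2L); hi <- min(binHi, k + 2L)
    k <- lo - 1L + which.max(raw[lo:hi])
    off <- if (k > 1 && k < length(raw) && all(raw[(k - 1):(k + 1)] > 0))
      .parabolicOffset(log(raw[k - 1]), log(raw[k]), log(raw[k + 1])) else 0
    freqs[k] + off * dF
  }
  for (i in seq_len(nf)) {
    if (!valid[i]) next
    f0 <- f0Track@f0Hz[i]
    t <- f0Track@timesS[i]
    # interpolate between the two spectrogram frames bracketing the voicing
    # frame center, so a fast FM sweep does not skew F1 against F0
    jAfter <- which(tf@timesS >= t)[1]
    if (is.na(jAfter)) {
      f1[i] <- f1At(length(tf@timesS), f0)
    } else if (jAfter == 1) {
      f1[i] <- f1At(1L, f0)
    } else {
      j0 <- jAfter - 1L
      wgt <- (t - tf@timesS[j0]) / (tf@timesS[jAfter] - tf@timesS[j0])
      f1[i] <- (1 - wgt) * f1At(j0, f0) + wgt * f1At(jAfter, f0)
    }
    if (is.na(f1[i]) || f1[i] <= f0) { f1[i] <- NA_real_; valid[i] <- FALSE }
  }
  ContourTrack(f0Track@timesS, ifelse(valid, f0Track@f0Hz, NA_real_),
               f1Hz = f1, valid = valid)
}

#' Per-call scalar features
#'
#' Reduces a call's tracks to the feature vector: duration, level, F0 mean /
#' max / SD, latency of the F0 maximum, and the F1/F0 harmonic-ratio mean /
#' SD / max, latency of the maximal ratio, and the ratio at the frame of
#' maximal F0. Track statistics use valid frames only; latencies are measured
#' from segment onset; the level is
#' \code{calibrationDb + 20 log10(RMS over the whole segment)}.
#'
#' @param segSignal numeric samples of the segment.
#' @param track \linkS4class{ContourTrack} with F0 and F1.
#' @param fs sampling rate (Hz).
#' @param calibrationDb dB SPL at full-scale RMS.
#' @return one-row data.frame with columns \code{duration_s}, \code{level_db},
#'   \code{f0_mean}, \code{f0_max}, \code{f0_sd}, \code{t_f0max_s},
#'   \code{hr_mean}, \code{hr_sd}, \code{hr_max}, \code{t_hrmax_s},
#'   \code{hr_at_f0max}.
#' @export
computeCallFeatures <- function(segSignal, track, fs, calibrationDb = 94) {
  ok <- track@valid & !is.na(track@f0Hz)
  if (sum(ok) < 3)
    stop("fewer than 3 valid frames; cannot compute features", call. = FALSE)
  f0 <- track@f0Hz[ok]
  t <- track@timesS[ok]
  hr <- if (length(track@f1Hz)) (track@f1Hz / track@f0Hz)[ok] else
    rep(NA_real_, sum(ok))
  iMax <- which.max(f0)
  data.frame(
    duration_s = length(segSignal) / fs,
    level_db = calibrationDb + 20 * log10(sqrt(mean(segSignal^2))),
    f0_mean = mean(f0), f0_max = f0[iMax], f0_sd = sd(f0),
    t_f0max_s = t[iMax],
    hr_mean = mean(hr), hr_sd = sd(hr), hr_max = max(hr),
    t_hrmax_s = t[which.max(hr)],
    hr_at_f0max = hr[iMax]
  )
}

#' Analyze a whole session end to end
#'
#' Runs the full per-session chain: high-pass filtering, sliding-RMS
#' detection, frame voicing with SIFT correction, call classification, and --
#' for voiced calls -- F0/F1 tracking and feature extraction. Unvoiced and
#' combined calls are retained in the table with their duration, level and
#' class but NA acoustic-structure features.
#'
#' @param rec a \linkS4class{SessionRecording}.
#' @param expectedF0MaxHz expected maximum F0 for the constrained pitch
#'   search (default 1000 Hz).
#' @param twoPass if TRUE, the expected F0 is re-estimated from the session's
#'   median first-pass maximum F0 and the tracks are recomputed.
#' @param rmsWindowS,rmsHopS,thresholdFactor,mergeGapS,minDurS detection
#'   parameters (see [slidingRms()], [sessionThreshold()],
#'   [detectSegments()]).
#' @param cutoffHz,filterOrder high-pass parameters.
#' @param sift apply SIFT correction to frame voicing.
#' @return data.frame with one row per detected call: \code{call_id},
#'   \code{onset_s}, \code{offset_s}, \code{duration_s}, \code{call_class},
#'   \code{voiced_frac}, \code{level_db} and the [computeCallFeatures()]
#'   columns. The detection threshold and segment count are attached as
#'   attributes \code{"threshold"} and \code{"nSegments"}.
#' @export
analyzeSession <- function(rec, expectedF0MaxHz = 1000, twoPass = FALSE,
                           rmsWindowS = 0.090, rmsHopS = 0.010,
                           thresholdFactor = 1.30, mergeGapS = 0.050,
                           minDurS = 0.030, cutoffHz = 500, filterOrder = 10,
                           sift = TRUE) {
  fs <- rec@fs
  y <- highpassFilter(rec@samples, fs, cutoffHz, filterOrder)
  track <- slidingRms(y, fs, rmsWindowS, rmsHopS)
  thr <- sessionThreshold(track, thresholdFactor)
  segs <- detectSegments(track, thr, mergeGapS, minDurS)
  out <- .analyzePass(y, segs, fs, rec@calibrationDb, expectedF0MaxHz, sift)
  if (twoPass) {
    med <- stats::median(out$f0_max, na.rm = TRUE)
    if (is.finite(med))
      out <- .analyzePass(y, segs, fs, rec@calibrationDb, med, sift)
  }
  attr(out, "threshold") <- thr
  attr(out, "nSegments") <- nrow(segs)
  out
}

.naFeatures <- data.frame(
  f0_mean = NA_real_, f0_max = NA_real_, f0_sd = NA_real_,
  t_f0max_s = NA_real_, hr_mean = NA_real_, hr_sd = NA_real_,
  hr_max = NA_real_, t_hrmax_s = NA_real_, hr_at_f0max = NA_real_)

.analyzePass <- function(y, segs, fs, calibrationDb, expectedF0MaxHz, sift) {
  rows <- lapply(seq_len(nrow(segs)), function(i) {
    x <- y[(segs$onset_sample[i] + 1):segs$offset_sample[i]]
    frames <- segmentFrames(x, fs, sift = sift)
    cls <- classifyCall(frames$voiced)
    base <- data.frame(
      call_id = i, onset_s = segs$onset_s[i], offset_s = segs$offset_s[i],
      duration_s = segs$duration_s[i], call_class = cls,
      voiced_frac = mean(frames$voiced),
      level_db = calibrationDb + 20 * log10(sqrt(mean(x^2))))
    feat <- .naFeatures
    if (cls == "voiced" && sum(frames$voiced) >= 3) {
      res <- try({
        f0t <- estimateF0Track(x, frames, fs, expectedF0MaxHz)
        ft <- estimateF1Track(x, f0t, fs)
        computeCallFeatures(x, ft, fs, calibrationDb)
      }, silent = TRUE)
      if (!inherits(res, "try-error"))
        feat <- res[, setdiff(names(res), c("duration_s", "level_db"))]
    }
    cbind(base, feat)
  })
  if (length(rows) == 0) {
    return(cbind(data.frame(call_id = integer(0), onset_s = numeric(0),
                            offset_s = numeric(0), duration_s = numeric(0),
                            call_class = character(0),
                            voiced_frac = numeric(0), level_db = numeric(0)),
                 .naFeatures[0, ]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
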