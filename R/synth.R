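#' Specify one synthetic kitten call
#'
#' Parameter bundle for the call simulator. A voiced call is a harmonic stack
#' whose fundamental follows a smooth contour: an optional raised onset FM
#' sweep (rise from \code{baseF0} to \code{baseF0 + sweepUp} and back within
#' the first \code{sweepFrac} of the call), then a hold at \code{baseF0}.
#' Harmonic amplitudes roll off at 6 dB per harmonic by default. Nonlinear
#' phenomena seen in real kitten isolation calls can be injected:
#' \describe{
#'   \item{subharmonic}{components at half-integer multiples of F0 (0.5, 1.5,
#'     2.5 x F0) at relative amplitude 0.35, active over a random interior
#'     stretch of the call.}
#'   \item{freq_jump}{an instantaneous F0 step (x1.2) at a random interior
#'     time.}
#'   \item{biphonation}{a second, independent harmonic stack at an
#'     incommensurate fundamental (0.77 x F0) at relative amplitude 0.7,
#'     active over a random interior stretch.}
#' }
#' Phenomena appear at varying latencies within real calls; windowing their
#' injection reproduces the within-call variability they cause in the
#' harmonic-ratio track.
#'
#' @param durationS call duration in seconds (0.05..2.5).
#' @param baseF0 fundamental frequency in Hz (kitten isolation calls: near
#'   1 kHz).
#' @param sweepUp onset FM rise extent in Hz (0 = no sweep).
#' @param sweepFrac fraction of the duration occupied by the up/down sweep
#'   (0..0.5).
#' @param nHarmonics number of harmonic components (k = 1 is the fundamental).
#' @param harmonicAmps relative amplitudes per harmonic; default
#'   \code{2^-(k-1)} (-6 dB/harmonic).
#' @param levelDb target call level in dB SPL (given the session calibration).
#' @param callClass "voiced", "unvoiced" or "combined".
#' @param phenomena character subset of
#'   \code{c("subharmonic", "freq_jump", "biphonation")}.
#' @param seed integer seed for the call's own randomness.
#' @return a validated list of class \code{"CallSpec"}.
#' @export
callSpec <- function(durationS = 0.5, baseF0 = 1000, sweepUp = 0,
                     sweepFrac = 0.2, nHarmonics = 5, harmonicAmps = NULL,
                     levelDb = 70, callClass = "voiced",
                     phenomena = character(0), seed = 1L) {
  if (durationS < 0.05 || durationS > 2.5)
    stop("durationS must be in [0.05, 2.5]", call. = FALSE)
  if (sweepFrac < 0 || sweepFrac > 0.5)
    stop("sweepFrac must be in [0, 0.5]", call. = FALSE)
  if (!callClass %in% c("voiced", "unvoiced", "combined"))
    stop("unknown callClass: ", callClass, call. = FALSE)
  bad <- setdiff(phenomena, c("subharmonic", "freq_jump", "biphonation"))
  if (length(bad)) stop("unknown phenomena: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (is.null(harmonicAmps)) harmonicAmps <- 2^-(seq_len(nHarmonics) - 1)
  stopifnot(length(harmonicAmps) == nHarmonics, baseF0 > 0)
  structure(list(
    durationS = durationS, baseF0 = baseF0, sweepUp = sweepUp,
    sweepFrac = sweepFrac, nHarmonics = nHarmonics,
    harmonicAmps = harmonicAmps, levelDb = levelDb, callClass = callClass,
    phenomena = phenomena, seed = as.integer(seed)), class = "CallSpec")
}

# Continuous F0 contour in Hz at times t (seconds from call onset).
# Raised-sine up/down sweep over [0, sweepFrac*duration], then base hold.
.f0At <- function(spec, t, jumpAtS = NA, jumpFactor = 1.2) {
  sweepDur <- spec$sweepFrac * spec$durationS
  f <- rep(spec$baseF0, length(t))
  if (spec$sweepUp > 0 && sweepDur > 0) {
    inSweep <- t >= 0 & t <= sweepDur
    f[inSweep] <- spec$baseF0 + spec$sweepUp * sin(pi * t[inSweep] / sweepDur)
  }
  if (!is.na(jumpAtS)) f[t >= jumpAtS] <- f[t >= jumpAtS] * jumpFactor
  f
}

#' Ground-truth F0 contour for a call spec
#'
#' Samples the simulator's continuous F0 contour at frame centers
#' (\code{frameDt/2, frameDt/2 + frameDt, ...}). When \code{sweepUp > 0} the
#' frame closest to the sweep midpoint is snapped to the exact contour peak
#' \code{baseF0 + sweepUp}, so the sampled track attains its nominal maximum at
#' a unique interior frame.
#'
#' @param spec a [callSpec()].
#' @param frameDt frame step in seconds (default 0.010).
#' @return a \linkS4class{ContourTrack} with F0 only.
#' @export
makeF0Contour <- function(spec, frameDt = 0.010) {
  stopifnot(inherits(spec, "CallSpec"), frameDt > 0)
  times <- seq(frameDt / 2, spec$durationS, by = frameDt)
  f0 <- .f0At(spec, times)
  if (spec$sweepUp > 0 && spec$sweepFrac > 0) {
    peakT <- spec$sweepFrac * spec$durationS / 2
    f0[which.min(abs(times - peakT))] <- spec$baseF0 + spec$sweepUp
  }
  ContourTrack(times, f0)
}

# Unit envelope that is 1 on [t1, t2] with 10-ms raised-cosine edges.
.windowEnvelope <- function(n, fs, t1, t2, rampS = 0.010) {
  t <- (seq_len(n) - 0.5) / fs
  env <- numeric(n)
  env[t >= t1 & t <= t2] <- 1
  up <- t >= t1 - rampS & t < t1
  env[up] <- 0.5 * (1 - cos(pi * (t[up] - t1 + rampS) / rampS))
  dn <- t > t2 & t <= t2 + rampS
  env[dn] <- 0.5 * (1 + cos(pi * (t[dn] - t2) / rampS))
  env
}

# 10-ms raised-cosine on/off ramps, in place.
.applyRamps <- function(x, fs, rampS = 0.010) {
  n <- length(x)
  nr <- min(round(rampS * fs), floor(n / 2))
  if (nr > 0) {
    r <- 0.5 * (1 - cos(pi * (seq_len(nr) - 0.5) / nr))
    x[1:nr] <- x[1:nr] * r
    x[(n - nr + 1):n] <- x[(n - nr + 1):n] * rev(r)
  }
  x
}

# Scale to the RMS implied by levelDb under the session calibration.
.scaleToLevel <- function(x, levelDb, calibrationDb = 94) {
  target <- 10^((levelDb - calibrationDb) / 20)
  r <- sqrt(mean(x^2))
  if (r == 0) stop("cannot scale a silent signal", call. = FALSE)
  x * (target / r)
}

# One harmonic stack following contour f0PerSample (Hz per sample).
.harmonicStack <- function(f0PerSample, fs, amps, phase0 = 0) {
  phase <- phase0 + 2 * pi * cumsum(f0PerSample) / fs
  w <- numeric(length(phase))
  for (k in seq_along(amps)) w <- w + amps[k] * sin(k * phase)
  w
}

#' Synthesize a voiced isolation call
#'
#' Generates the harmonic-stack waveform for a voiced [callSpec()]: phase is
#' the integral of the F0 contour, harmonics are summed with the spec's
#' amplitudes, phenomena are injected as described in [callSpec()], 10-ms
#' raised-cosine ramps shape the edges, and the result is scaled to the target
#' level.
#'
#' @param spec a voiced [callSpec()].
#' @param fs sampling rate (Hz).
#' @param calibrationDb dB SPL at full-scale RMS (default 94).
#' @return list: \code{wave} (numeric), \code{jumpAtS} (NA or the F0 step
#'   time), \code{f0Fun} (function of time giving the realized F0 contour).
#' @export
synthVoicedCall <- function(spec, fs, calibrationDb = 94) {
  stopifnot(inherits(spec, "CallSpec"))
  if (spec$callClass != "voiced")
    stop("spec is not a voiced call", call. = FALSE)
  maxF0 <- spec$baseF0 + max(0, spec$sweepUp)
  jumpFactor <- 1.2
  if ("freq_jump" %in% spec$phenomena) maxF0 <- maxF0 * jumpFactor
  if (maxF0 * spec$nHarmonics >= fs / 2)
    stop("aliasing violation: harmonics exceed Nyquist", call. = FALSE)

  set.seed(spec$seed)
  n <- round(spec$durationS * fs)
  t <- (seq_len(n) - 0.5) / fs
  jumpAtS <- if ("freq_jump" %in% spec$phenomena)
    runif(1, 0.2, 0.8) * spec$durationS else NA
  f0s <- .f0At(spec, t, jumpAtS = jumpAtS, jumpFactor = jumpFactor)
  w <- .harmonicStack(f0s, fs, spec$harmonicAmps)

  # Nonlinear phenomena occupy a random interior stretch of the call (they
  # appear at varying latencies in real calls); the envelope has 10-ms
  # raised-cosine edges so the injected components do not click.
  if (length(intersect(c("subharmonic", "biphonation"), spec$phenomena))) {
    startFrac <- runif(1, 0.15, 0.45)
    lenFrac <- runif(1, 0.30, 0.45)
    env <- .windowEnvelope(n, fs, startFrac * spec$durationS,
                           min(spec$durationS,
                               (startFrac + lenFrac) * spec$durationS))
    if ("subharmonic" %in% spec$phenomena) {
      # components at 0.5, 1.5, 2.5 x F0 interleaving the stack; amplitude
      # kept moderate so the fundamental period still dominates the pitch lag
      subAmp <- 0.35 * spec$harmonicAmps[1]
      phase <- 2 * pi * cumsum(f0s) / fs
      for (m in c(0.5, 1.5, 2.5)) w <- w + env * subAmp * sin(m * phase)
    }
    if ("biphonation" %in% spec$phenomena) {
      f2 <- f0s * 0.77
      nh2 <- min(3, spec$nHarmonics)
      w <- w + env * 0.7 *
        .harmonicStack(f2, fs, spec$harmonicAmps[seq_len(nh2)],
                       phase0 = runif(1, 0, 2 * pi))
    }
  }
  w <- .applyRamps(w, fs)
  w <- .scaleToLevel(w, spec$levelDb, calibrationDb)
  f0Fun <- function(tt) .f0At(spec, tt, jumpAtS = jumpAtS,
                              jumpFactor = jumpFactor)
  list(wave = w, jumpAtS = jumpAtS, f0Fun = f0Fun)
}

#' Synthesize an unvoiced (purr-like) call
#'
#' Band-limited Gaussian noise (0.5-8 kHz) with slow amplitude modulation
#' (20-30 Hz, depth 0.8), 10-ms ramps, scaled exactly to the target RMS level.
#' The waveform is aperiodic by construction: its normalized autocorrelation
#' in the pitch lag range stays well below the 0.6 voicing criterion.
#'
#' @param durationS duration in seconds.
#' @param levelDb target level (dB SPL).
#' @param fs sampling rate (Hz).
#' @param seed integer seed.
#' @param calibrationDb dB SPL at full-scale RMS.
#' @return numeric waveform of \code{round(durationS * fs)} samples.
#' @export
synthUnvoicedCall <- function(durationS, levelDb, fs, seed = 1L,
                              calibrationDb = 94) {
  stopifnot(durationS > 0)
  set.seed(seed)
  n <- round(durationS * fs)
  x <- rnorm(n)
  x <- bandpassFilter(x, fs, 500, min(8000, 0.45 * fs))
  fAm <- runif(1, 20, 30)
  t <- (seq_len(n) - 0.5) / fs
  x <- x * (1 + 0.8 * sin(2 * pi * fAm * t + runif(1, 0, 2 * pi)))
  x <- .applyRamps(x, fs)
  .scaleToLevel(x, levelDb, calibrationDb)
}

#' Synthesize a combined call (unvoiced onset, voiced continuation)
#'
#' @param specs list of exactly two [callSpec()]s: one unvoiced followed by
#'   one voiced.
#' @param fs sampling rate (Hz).
#' @param calibrationDb dB SPL at full-scale RMS.
#' @return list: \code{wave}, \code{boundaryS} (time of the unvoiced-to-voiced
#'   transition, center of the 10-ms crossfade), \code{f0Fun} of the voiced
#'   part (time measured from the call onset).
#' @export
synthCombinedCall <- function(specs, fs, calibrationDb = 94) {
  if (length(specs) != 2 ||
      specs[[1]]$callClass != "unvoiced" || specs[[2]]$callClass != "voiced")
    stop("specs must be one unvoiced part followed by one voiced part",
         call. = FALSE)
  u <- synthUnvoicedCall(specs[[1]]$durationS, specs[[1]]$levelDb, fs,
                         seed = specs[[1]]$seed, calibrationDb = calibrationDb)
  v <- synthVoicedCall(specs[[2]], fs, calibrationDb = calibrationDb)
  nCf <- round(0.010 * fs)
  nU <- length(u); nV <- length(v$wave)
  stopifnot(nU > nCf, nV > nCf)
  w <- numeric(nU + nV - nCf)
  w[seq_len(nU)] <- u
  fade <- 0.5 * (1 - cos(pi * (seq_len(nCf) - 0.5) / nCf))
  idx <- (nU - nCf + 1):nU
  w[idx] <- u[idx] * (1 - fade) + v$wave[seq_len(nCf)] * fade
  w[(nU + 1):(nU + nV - nCf)] <- v$wave[(nCf + 1):nV]
  boundaryS <- (nU - nCf / 2) / fs
  voicedOnsetS <- (nU - nCf) / fs
  f0Fun <- function(tt) v$f0Fun(tt - voicedOnsetS)
  list(wave = w, boundaryS = boundaryS, f0Fun = f0Fun)
}
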