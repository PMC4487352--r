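#' SessionRecording: one session of audio plus metadata
#'
#' Container for a mono session waveform. Amplitudes are dimensionless
#' full-scale units in [-1, 1]; \code{calibrationDb} gives the sound pressure
#' level (dB SPL) that corresponds to an RMS of 1.0 full-scale, so the level of
#' any stretch of signal is \code{calibrationDb + 20*log10(rms)}.
#'
#' @slot samples numeric vector, finite, |x| <= 1.
#' @slot fs sampling rate in Hz.
#' @slot calibrationDb dB SPL at RMS 1.0 full-scale (default 94).
#' @slot animalId,sessionId opaque identifiers.
#' @slot group one of \code{"hearing"}, \code{"impaired"}, \code{"deaf"}.
#' @slot postnatalDay integer age in days (1..365).
#' @exportClass SessionRecording
setClass("SessionRecording",
  representation(
    samples = "numeric",
    fs = "numeric",
    calibrationDb = "numeric",
    animalId = "character",
    group = "character",
    postnatalDay = "integer",
    sessionId = "character"
  ),
  prototype(
    calibrationDb = 94,
    animalId = "unknown",
    group = "hearing",
    postnatalDay = 30L,
    sessionId = "session-1"
  )
)

setValidity("SessionRecording", function(object) {
  msg <- character()
  if (length(object@fs) != 1 || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(object@samples) && !all(is.finite(object@samples))) {
    msg <- c(msg, "all samples must be finite")
  } else if (length(object@samples) && max(abs(object@samples)) > 1 + 1e-9) {
    msg <- c(msg, "samples must lie in [-1, 1] full-scale")
  }
  if (!object@group %in% c("hearing", "impaired", "deaf"))
    msg <- c(msg, "group must be one of hearing/impaired/deaf")
  if (length(object@postnatalDay) != 1 ||
      object@postnatalDay < 1L || object@postnatalDay > 365L)
    msg <- c(msg, "postnatalDay must be in [1, 365]")
  if (length(msg)) msg else TRUE
})

#' Construct a SessionRecording
#'
#' @param samples numeric waveform, full-scale units in [-1, 1].
#' @param fs sampling rate (Hz).
#' @param calibrationDb dB SPL corresponding to RMS 1.0 full-scale.
#' @param animalId,sessionId identifiers.
#' @param group hearing-status group (\code{"hearing"}, \code{"impaired"},
#'   \code{"deaf"}).
#' @param postnatalDay age in postnatal days.
#' @return A \linkS4class{SessionRecording}.
#' @examples
#' rec <- SessionRecording(sin(2 * pi * 1000 * (0:4409) / 44100), fs = 44100)
#' duration(rec)
#' @export
SessionRecording <- function(samples, fs, calibrationDb = 94,
                             animalId = "unknown", group = "hearing",
                             postnatalDay = 30L, sessionId = "session-1") {
  new("SessionRecording",
    samples = as.numeric(samples), fs = as.numeric(fs),
    calibrationDb = as.numeric(calibrationDb),
    animalId = as.character(animalId), group = as.character(group),
    postnatalDay = as.integer(postnatalDay), sessionId = as.character(sessionId))
}

#' Spectrogram: a time-frequency power representation
#'
#' @slot power frequency x time matrix of linear power (rows = frequency bins).
#' @slot timesS frame-center times in seconds.
#' @slot freqsHz bin-center frequencies in Hz.
#' @slot params list of analysis parameters (window, overlap, nfft, fs, ...).
#' @exportClass Spectrogram
setClass("Spectrogram",
  representation(
    power = "matrix",
    timesS = "numeric",
    freqsHz = "numeric",
    params = "list"
  )
)

setValidity("Spectrogram", function(object) {
  msg <- character()
  if (nrow(object@power) != length(object@freqsHz))
    msg <- c(msg, "nrow(power) must equal length(freqsHz)")
  if (ncol(object@power) != length(object@timesS))
    msg <- c(msg, "ncol(power) must equal length(timesS)")
  if (length(object@power) && min(object@power, na.rm = TRUE) < 0)
    msg <- c(msg, "power must be non-negative")
  if (length(msg)) msg else TRUE
})

#' ContourTrack: per-frame F0/F1 trajectories
#'
#' Frame-wise fundamental (F0) and first-harmonic (F1) frequency tracks over a
#' single call. Invalid frames (unvoiced, or tracking confidence below the
#' floor) carry \code{NA} and \code{valid = FALSE}.
#'
#' @slot timesS frame-center times in seconds from call onset.
#' @slot f0Hz per-frame fundamental frequency (NA where invalid).
#' @slot f1Hz per-frame first-harmonic frequency (NA where invalid).
#' @slot valid logical per frame.
#' @exportClass ContourTrack
setClass("ContourTrack",
  representation(
    timesS = "numeric",
    f0Hz = "numeric",
    f1Hz = "numeric",
    valid = "logical"
  )
)

setValidity("ContourTrack", function(object) {
  n <- length(object@timesS)
  msg <- character()
  if (length(object@f0Hz) != n || length(object@valid) != n)
    msg <- c(msg, "timesS, f0Hz and valid must have equal length")
  if (length(object@f1Hz) && length(object@f1Hz) != n)
    msg <- c(msg, "f1Hz must be empty or match timesS in length")
  ok <- object@valid & !is.na(object@f0Hz)
  if (any(ok) && any(object@f0Hz[ok] <= 0))
    msg <- c(msg, "f0 must be positive wherever valid")
  if (length(object@f1Hz)) {
    both <- ok & !is.na(object@f1Hz)
    if (any(both) && any(object@f1Hz[both] <= object@f0Hz[both]))
      msg <- c(msg, "f1 must exceed f0 wherever both are valid")
  }
  if (length(msg)) msg else TRUE
})

ContourTrack <- function(timesS, f0Hz, f1Hz = numeric(0), valid = !is.na(f0Hz)) {
  new("ContourTrack", timesS = as.numeric(timesS), f0Hz = as.numeric(f0Hz),
      f1Hz = as.numeric(f1Hz), valid = as.logical(valid))
}
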