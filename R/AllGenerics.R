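#' @name accessors
#' @title Accessors for SessionRecording and Spectrogram objects
#' @param x an object.
#' @param object an object (for \code{show}).
#' @return \code{samples}: numeric waveform; \code{samplingRate}: Hz;
#'   \code{duration}: seconds; \code{calibrationDb}: dB SPL at full-scale RMS;
#'   \code{spectroPower}/\code{spectroTimes}/\code{spectroFreqs}: the matrix
#'   and axes of a \linkS4class{Spectrogram}.
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))
#' @rdname accessors
#' @export
setGeneric("calibrationDb", function(x) standardGeneric("calibrationDb"))
#' @rdname accessors
#' @export
setGeneric("spectroPower", function(x) standardGeneric("spectroPower"))
#' @rdname accessors
#' @export
setGeneric("spectroTimes", function(x) standardGeneric("spectroTimes"))
#' @rdname accessors
#' @export
setGeneric("spectroFreqs", function(x) standardGeneric("spectroFreqs"))

#' @rdname accessors
setMethod("samples", "SessionRecording", function(x) x@samples)
#' @rdname accessors
setMethod("samplingRate", "SessionRecording", function(x) x@fs)
#' @rdname accessors
setMethod("duration", "SessionRecording",
          function(x) length(x@samples) / x@fs)
#' @rdname accessors
setMethod("calibrationDb", "SessionRecording", function(x) x@calibrationDb)

#' @rdname accessors
setMethod("spectroPower", "Spectrogram", function(x) x@power)
#' @rdname accessors
setMethod("spectroTimes", "Spectrogram", function(x) x@timesS)
#' @rdname accessors
setMethod("spectroFreqs", "Spectrogram", function(x) x@freqsHz)

#' @rdname accessors
setMethod("show", "SessionRecording", function(object) {
  cat(sprintf(
    "SessionRecording '%s' (%s, day %d)\n  %d samples @ %g Hz = %.2f s, calibration %.1f dB SPL @ FS RMS\n",
    object@sessionId, object@group, object@postnatalDay,
    length(object@samples), object@fs,
    length(object@samples) / object@fs, object@calibrationDb))
})

#' @rdname accessors
setMethod("show", "Spectrogram", function(object) {
  cat(sprintf(
    "Spectrogram: %d freq bins x %d frames, %.0f-%.0f Hz, %.3f-%.3f s\n",
    nrow(object@power), ncol(object@power),
    min(object@freqsHz), max(object@freqsHz),
    if (length(object@timesS)) min(object@timesS) else NA_real_,
    if (length(object@timesS)) max(object@timesS) else NA_real_))
})

#' @rdname accessors
setMethod("show", "ContourTrack", function(object) {
  nv <- sum(object@valid)
  cat(sprintf("ContourTrack: %d frames (%d valid), F0 median %.0f Hz%s\n",
    length(object@timesS), nv,
    if (nv) stats::median(object@f0Hz[object@valid]) else NA_real_,
    if (length(object@f1Hz)) " (+F1)" else ""))
})
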