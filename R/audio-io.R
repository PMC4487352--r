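#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader for the session recordings handled by this
#' package: mono, 16-bit PCM or 32-bit IEEE float. Unknown chunks are skipped.
#' PCM samples are scaled to full-scale [-1, 1] by dividing by 32768.
#'
#' @param path path to a .wav file.
#' @return list with \code{samples} (numeric, full-scale) and \code{fs} (Hz).
#' @seealso [loadSession()] for the metadata-carrying wrapper, [saveWav()].
#' @export
readWav <- function(path) {
  if (!file.exists(path)) stop("WAV file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, "integer", 1, 4, endian = "little")   # RIFF size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)

  fmt <- NULL
  dat <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      audioFormat <- readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      nChannels   <- readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      sampleRate  <- readBin(con, "integer", 1, 4, endian = "little")
      readBin(con, "integer", 1, 4, endian = "little")  # byte rate
      readBin(con, "integer", 1, 2, endian = "little")  # block align
      bits <- readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      if (sz > 16) readBin(con, "raw", sz - 16)
      fmt <- list(format = audioFormat, channels = nChannels,
                  fs = sampleRate, bits = bits)
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data before fmt", call. = FALSE)
      dat <- readBin(con, "raw", sz)
      if (sz %% 2 == 1) readBin(con, "raw", 1)  # chunk padding
      break
    } else {
      readBin(con, "raw", sz + sz %% 2)  # skip unknown chunk (padded)
    }
  }
  if (is.null(fmt) || is.null(dat))
    stop("malformed WAV (missing fmt or data chunk): ", path, call. = FALSE)
  if (fmt$channels != 1)
    stop("only mono WAV is supported (got ", fmt$channels, " channels)",
         call. = FALSE)
  if (fmt$format == 1 && fmt$bits == 16) {
    x <- readBin(dat, "integer", length(dat) / 2, 2, endian = "little") / 32768
  } else if (fmt$format == 3 && fmt$bits == 32) {
    x <- readBin(dat, "double", length(dat) / 4, 4, endian = "little")
  } else {
    stop("unsupported WAV encoding (format ", fmt$format, ", ",
         fmt$bits, " bits); use PCM16 or float32", call. = FALSE)
  }
  if (length(x) == 0) stop("zero-length audio in ", path, call. = FALSE)
  list(samples = x, fs = fmt$fs)
}

#' Write a mono WAV file
#'
#' @param samples numeric waveform, full-scale [-1, 1]. Values outside are
#'   clipped for PCM16.
#' @param fs sampling rate (Hz).
#' @param path output path.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @return invisibly, the path.
#' @export
saveWav <- function(samples, fs, path, bits = 16) {
  stopifnot(bits %in% c(16, 32), fs > 0, length(samples) > 0)
  bytesPerSample <- bits / 8
  dataSize <- length(samples) * bytesPerSample
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + dataSize), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(as.integer(if (bits == 16) 1 else 3), con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(as.integer(fs), con, 4, endian = "little")
  writeBin(as.integer(fs * bytesPerSample), con, 4, endian = "little")
  writeBin(as.integer(bytesPerSample), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataSize), con, 4, endian = "little")
  if (bits == 16) {
    q <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
    writeBin(q, con, 2, endian = "little")
  } else {
    writeBin(as.numeric(samples), con, 4, endian = "little")
  }
  invisible(path)
}

#' Load a session recording from a WAV file
#'
#' Reads a mono WAV file and attaches session metadata, producing the
#' \linkS4class{SessionRecording} object the rest of the pipeline consumes.
#'
#' @inheritParams readWav
#' @param animalId,sessionId identifiers.
#' @param group hearing-status group.
#' @param postnatalDay age in postnatal days.
#' @param calibrationDb dB SPL at RMS 1.0 full-scale (default 94).
#' @return A \linkS4class{SessionRecording}.
#' @export
loadSession <- function(path, animalId = "unknown", group = "hearing",
                        postnatalDay = 30L, sessionId = basename(path),
                        calibrationDb = 94) {
  w <- readWav(path)
  SessionRecording(w$samples, w$fs, calibrationDb = calibrationDb,
                   animalId = animalId, group = group,
                   postnatalDay = postnatalDay, sessionId = sessionId)
}

.featureColumns <- c(
  "call_id", "onset_s", "offset_s", "duration_s", "call_class", "level_db",
  "f0_mean", "f0_max", "f0_sd", "t_f0max_s",
  "hr_mean", "hr_sd", "hr_max", "t_hrmax_s", "hr_at_f0max"
)

#' Write / read the per-call feature table
#'
#' Delimited text (CSV) with a fixed column order and a comment header line
#' documenting units. Numeric values are written with enough digits to
#' round-trip at 6 significant figures or better.
#'
#' @param features data.frame of per-call features (one row per call), as
#'   returned by [analyzeSession()].
#' @param path output path.
#' @return \code{writeCallTable}: invisibly, the path.
#' @export
writeCallTable <- function(features, path) {
  if (!is.data.frame(features) || nrow(features) == 0)
    stop("features must be a non-empty data.frame", call. = FALSE)
  missing <- setdiff(.featureColumns, names(features))
  if (length(missing))
    stop("features table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error"))
    stop("cannot open for writing: ", path, call. = FALSE)
  on.exit(close(con))
  writeLines(paste(
    "# isocall features: times in s, frequencies in Hz, level in dB SPL,",
    "harmonic ratio dimensionless"), con)
  df <- features[, .featureColumns]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 8))
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCallTable
#' @return \code{readCallTable}: the feature data.frame.
#' @export
readCallTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
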