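#' Sliding RMS track of a session
#'
#' Moves a window (default 90 ms) over the signal in steps of \code{hopS}
#' (default 10 ms) and computes the RMS within each window position. The value
#' at position \code{t} is the RMS of samples in \code{[t, t + window)}.
#' Computed via a cumulative sum of squares, so cost is linear in the signal.
#'
#' @param x numeric signal (or a \linkS4class{SessionRecording}).
#' @param fs sampling rate (Hz; ignored for recordings).
#' @param windowS window length in seconds (default 0.090).
#' @param hopS hop between window positions in seconds (default 0.010).
#' @return list of class \code{"RmsTrack"}: \code{values} (RMS per position,
#'   full-scale units), \code{timesS} (window start times), \code{windowS},
#'   \code{hopS}, \code{fs}.
#' @export
slidingRms <- function(x, fs, windowS = 0.090, hopS = 0.010) {
  if (is(x, "SessionRecording")) { fs <- x@fs; x <- x@samples }
  win <- max(1L, round(windowS * fs))
  hop <- max(1L, round(hopS * fs))
  n <- length(x)
  if (n < win) stop("signal shorter than the RMS window", call. = FALSE)
  cs <- c(0, cumsum(x^2))
  starts <- seq(1L, n - win + 1L, by = hop)
  values <- sqrt((cs[starts + win] - cs[starts]) / win)
  values <- pmax(values, 0)   # guard tiny negative from rounding
  structure(list(values = values, timesS = (starts - 1L) / fs,
                 windowS = win / fs, hopS = hop / fs, fs = fs),
            class = "RmsTrack")
}

#' Session detection threshold
#'
#' The threshold is \code{factor} (default 1.30, i.e. 130 \%) times the
#' minimum RMS value observed in the session -- the quietest window is taken
#' as the background-noise reference. A track containing digital silence
#' (minimum exactly 0) would give a useless zero threshold; in that case the
#' smallest positive value is used instead and a warning is raised.
#'
#' @param track an \code{"RmsTrack"} from [slidingRms()].
#' @param factor multiplier on the session minimum (default 1.30).
#' @return threshold RMS amplitude (full-scale units).
#' @export
sessionThreshold <- function(track, factor = 1.30) {
  stopifnot(inherits(track, "RmsTrack"), length(track$values) > 0)
  m <- min(track$values)
  if (m == 0) {
    pos <- track$values[track$values > 0]
    if (length(pos) == 0) {
      warning("track is all zero; threshold 0")
      return(0)
    }
    warning("session contains digital silence; threshold based on smallest positive RMS")
    m <- min(pos)
  }
  factor * m
}

#' Detect call segments from an RMS track
#'
#' Maximal runs of RMS positions above the threshold become candidate
#' segments. Runs separated by less than \code{mergeGapS} are merged (to curb
#' splitting of single vocalizations), and runs shorter than \code{minDurS}
#' are discarded. Sample boundaries are placed, by default, at the centers of
#' the first and last above-threshold RMS windows (\code{boundary =
#' "center"}), which bounds the boundary error by half an RMS window; the
#' outer convention (run start to run end + window) is available as
#' \code{boundary = "outer"}.
#'
#' @param track an \code{"RmsTrack"}.
#' @param threshold RMS threshold from [sessionThreshold()].
#' @param mergeGapS merge runs closer than this (default 0.050 s).
#' @param minDurS discard runs shorter than this (default 0.030 s).
#' @param boundary \code{"center"} (default) or \code{"outer"}.
#' @return data.frame of class segments: \code{onset_sample},
#'   \code{offset_sample} (0-based, half-open), \code{onset_s},
#'   \code{offset_s}, \code{duration_s}, \code{peak_rms}. Sorted, disjoint.
#' @export
detectSegments <- function(track, threshold, mergeGapS = 0.050,
                           minDurS = 0.030, boundary = c("center", "outer")) {
  stopifnot(inherits(track, "RmsTrack"), threshold >= 0)
  boundary <- match.arg(boundary)
  above <- track$values > threshold
  empty <- data.frame(onset_sample = integer(0), offset_sample = integer(0),
                      onset_s = numeric(0), offset_s = numeric(0),
                      duration_s = numeric(0), peak_rms = numeric(0))
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])

  # merge runs separated by < mergeGapS
  if (nrow(runs) > 1) {
    gapPos <- ceiling(mergeGapS / track$hopS)
    keep <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      if ((runs$start[i] - keep$end[nrow(keep)] - 1L) < gapPos) {
        keep$end[nrow(keep)] <- runs$end[i]
      } else {
        keep <- rbind(keep, runs[i, ])
      }
    }
    runs <- keep
  }
  # discard short runs
  runDur <- (runs$end - runs$start + 1L) * track$hopS
  runs <- runs[runDur >= minDurS, , drop = FALSE]
  if (nrow(runs) == 0) return(empty)

  fs <- track$fs
  hopSm <- round(track$hopS * fs)
  winSm <- round(track$windowS * fs)
  half <- round(winSm / 2)
  if (boundary == "center") {
    onset <- (runs$start - 1L) * hopSm + half
    offset <- (runs$end - 1L) * hopSm + half
  } else {
    onset <- (runs$start - 1L) * hopSm
    offset <- (runs$end - 1L) * hopSm + winSm
  }
  onset <- pmax(0L, as.integer(onset))
  data.frame(
    onset_sample = onset, offset_sample = as.integer(offset),
    onset_s = onset / fs, offset_s = offset / fs,
    duration_s = (offset - onset) / fs,
    peak_rms = vapply(seq_len(nrow(runs)), function(i)
      max(track$values[runs$start[i]:runs$end[i]]), numeric(1))
  )
}

#' Eligibility of a call for average-spectrogram construction
#'
#' Only clean voiced calls enter the onset-aligned average spectrogram:
#' unvoiced and combined vocalizations are excluded, as are calls shorter
#' than 100 ms or longer than 1500 ms.
#'
#' @param callClass classification of the segment ("voiced", "unvoiced",
#'   "combined" or "unclassified").
#' @param durationS segment duration in seconds.
#' @return TRUE iff the call may enter the average spectrogram.
#' @export
spectrogramEligibility <- function(callClass, durationS) {
  if (is.na(callClass) || callClass == "unclassified")
    stop("segment must be classified before the eligibility check",
         call. = FALSE)
  callClass == "voiced" & durationS >= 0.100 & durationS <= 1.500
}

#' Match detected segments against ground truth
#'
#' Greedy one-to-one matching of detected to true calls: a pair matches when
#' the detected segment overlaps the true call in time. Used to score
#' detection recall / precision and boundary error against simulator truth.
#'
#' @param detected data.frame with onset_s / offset_s (from
#'   [detectSegments()]).
#' @param truth data.frame with onset_s / offset_s (from
#'   [assembleSession()]).
#' @return list: \code{recall}, \code{precision} (fractions),
#'   \code{pairs} data.frame with per-match onset/offset errors in seconds.
#' @export
matchSegments <- function(detected, truth) {
  nd <- nrow(detected); nt <- nrow(truth)
  usedD <- rep(FALSE, nd)
  rows <- list()
  for (i in seq_len(nt)) {
    ovl <- which(!usedD &
                 detected$onset_s < truth$offset_s[i] &
                 detected$offset_s > truth$onset_s[i])
    if (length(ovl)) {
      j <- ovl[which.max(pmin(detected$offset_s[ovl], truth$offset_s[i]) -
                         pmax(detected$onset_s[ovl], truth$onset_s[i]))]
      usedD[j] <- TRUE
      rows[[length(rows) + 1]] <- data.frame(
        truth_id = i, det_id = j,
        onset_err_s = detected$onset_s[j] - truth$onset_s[i],
        offset_err_s = detected$offset_s[j] - truth$offset_s[i])
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(truth_id = integer(0), det_id = integer(0),
               onset_err_s = numeric(0), offset_err_s = numeric(0))
  list(recall = if (nt) nrow(pairs) / nt else NA_real_,
       precision = if (nd) nrow(pairs) / nd else NA_real_,
       pairs = pairs)
}
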