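#' Specify a cohort of synthetic sessions
#'
#' Describes the study conditions a simulated session is drawn from: hearing
#' group, age bin, number of calls, the F0-by-age schedule, group level
#' offsets, and how persistent the juvenile onset FM sweep is. The defaults
#' emulate the qualitative developmental picture in kitten isolation calls:
#' F0 near 1 kHz declining with age (schedule 1100/1000/900/800 Hz at
#' 1/1.5/2/3 months), an onset sweep that disappears by 2 months in hearing
#' animals but persists in deaf ones, deaf calls about 10 dB louder, and a
#' class mix dominated by voiced calls.
#'
#' @param group "hearing", "impaired" or "deaf".
#' @param ageMonths one of 1, 1.5, 2, 3.
#' @param callsPerSession number of calls (1..1000; realistic sessions carry
#'   200-600).
#' @param f0ByAge named numeric: month -> Hz.
#' @param sweepByAge named numeric: month -> onset sweep extent in Hz for
#'   groups whose sweep matures away.
#' @param levelOffsetDb additive group offset on call level (dB).
#' @param baseLevelDb mean call level before the offset (dB SPL).
#' @param f0Sd across-call F0 jitter (Hz).
#' @param levelSd across-call level jitter (dB).
#' @param ampJitterDb SD (dB) of per-call jitter on the amplitudes of the
#'   harmonics above the fundamental; larger values give the unstable
#'   ("smeared") harmonic structure of hearing-deprived calls.
#' @param sweepPersistence if TRUE the onset sweep keeps its juvenile extent
#'   at all ages (deaf preset).
#' @param phenomenaProb probability a voiced call carries one nonlinear
#'   phenomenon (subharmonic / frequency jump / biphonation, equiprobable).
#' @param classProbs named probabilities for voiced/unvoiced/combined.
#' @param seed master seed; per-call seeds are derived as
#'   \code{(seed + 104729 * callIndex) mod (2^31 - 1)} so individual calls are
#'   reproducible in isolation.
#' @return a validated list of class \code{"CohortSpec"}.
#' @export
cohortSpec <- function(group = "hearing", ageMonths = 1,
                       callsPerSession = 400,
                       f0ByAge = c("1" = 1100, "1.5" = 1000,
                                   "2" = 900, "3" = 800),
                       sweepByAge = c("1" = 300, "1.5" = 200,
                                      "2" = 50, "3" = 0),
                       levelOffsetDb = 0, baseLevelDb = 70,
                       f0Sd = 40, levelSd = 3, ampJitterDb = 2,
                       sweepPersistence = FALSE,
                       phenomenaProb = 0.08,
                       classProbs = c(voiced = 0.86, unvoiced = 0.07,
                                      combined = 0.07),
                       seed = 1L) {
  stopifnot(group %in% c("hearing", "impaired", "deaf"),
            ageMonths %in% c(1, 1.5, 2, 3))
  if (callsPerSession < 0 || callsPerSession > 1000)
    stop("callsPerSession must be in [0, 1000]", call. = FALSE)
  stopifnot(all(c("1", "1.5", "2", "3") %in% names(f0ByAge)),
            abs(sum(classProbs) - 1) < 1e-9)
  structure(list(
    group = group, ageMonths = ageMonths, callsPerSession = callsPerSession,
    f0ByAge = f0ByAge, sweepByAge = sweepByAge,
    levelOffsetDb = levelOffsetDb, baseLevelDb = baseLevelDb,
    f0Sd = f0Sd, levelSd = levelSd, ampJitterDb = ampJitterDb,
    sweepPersistence = sweepPersistence,
    phenomenaProb = phenomenaProb, classProbs = classProbs,
    seed = as.integer(seed)), class = "CohortSpec")
}

#' Group presets for the simulator
#'
#' \code{"hearing"}: baseline. \code{"impaired"}: a lower voiced fraction,
#' increased F0 jitter and moderately unstable harmonic amplitudes.
#' \code{"deaf"}: +10 dB level offset, persistent onset FM sweep at all ages,
#' a higher rate of nonlinear phenomena and the largest harmonic-amplitude
#' jitter -- the directions reported for congenitally deaf kittens.
#'
#' @param group "hearing", "impaired" or "deaf".
#' @param ageMonths age bin (1, 1.5, 2, 3).
#' @param ... overrides passed to [cohortSpec()].
#' @return a \code{"CohortSpec"}.
#' @export
groupPreset <- function(group, ageMonths = 1, ...) {
  base <- switch(group,
    hearing  = list(),
    impaired = list(f0Sd = 60, ampJitterDb = 4,
                    classProbs = c(voiced = 0.70, unvoiced = 0.15,
                                   combined = 0.15)),
    deaf     = list(levelOffsetDb = 10, sweepPersistence = TRUE,
                    phenomenaProb = 0.30, f0Sd = 50, ampJitterDb = 6),
    stop("unknown group: ", group, call. = FALSE))
  do.call(cohortSpec,
          c(list(group = group, ageMonths = ageMonths),
            utils::modifyList(base, list(...))))
}

.perCallSeed <- function(masterSeed, i) {
  as.integer((as.numeric(masterSeed) + 104729 * i) %% (2^31 - 1))
}

# Draw the per-call specs for a cohort session. Returns a list of entries
# with $spec (CallSpec or list of two for combined) and $class.
.drawCallSpecs <- function(cohort) {
  set.seed(cohort$seed)
  n <- cohort$callsPerSession
  ageKey <- as.character(cohort$ageMonths)
  f0Age <- cohort$f0ByAge[[ageKey]]
  sweep <- if (cohort$sweepPersistence) cohort$sweepByAge[["1"]]
           else cohort$sweepByAge[[ageKey]]
  classes <- sample(names(cohort$classProbs), n, replace = TRUE,
                    prob = cohort$classProbs)
  durs <- pmin(2, pmax(0.12, 0.15 + rgamma(n, shape = 2, scale = 0.18)))
  f0s <- pmax(400, rnorm(n, f0Age, cohort$f0Sd))
  levels <- rnorm(n, cohort$baseLevelDb + cohort$levelOffsetDb, cohort$levelSd)
  hasPhen <- runif(n) < cohort$phenomenaProb
  phenKind <- sample(c("subharmonic", "freq_jump", "biphonation"), n,
                     replace = TRUE)
  leadDurs <- runif(n, 0.12, 0.35)   # unvoiced lead of combined calls
  nH <- 5
  ampJit <- matrix(rnorm(n * (nH - 1), 0, cohort$ampJitterDb), n, nH - 1)
  lapply(seq_len(n), function(i) {
    sd <- .perCallSeed(cohort$seed, i)
    cls <- classes[i]
    amps <- c(1, 2^-(seq_len(nH - 1)) * 10^(ampJit[i, ] / 20))
    if (cls == "voiced") {
      spec <- callSpec(durationS = durs[i], baseF0 = f0s[i], sweepUp = sweep,
                       sweepFrac = if (sweep > 0) 0.25 else 0,
                       nHarmonics = nH, harmonicAmps = amps,
                       levelDb = levels[i], callClass = "voiced",
                       phenomena = if (hasPhen[i]) phenKind[i] else character(0),
                       seed = sd)
    } else if (cls == "unvoiced") {
      spec <- callSpec(durationS = durs[i], levelDb = levels[i] - 6,
                       callClass = "unvoiced", seed = sd)
    } else {
      spec <- list(
        callSpec(durationS = leadDurs[i], levelDb = levels[i] - 6,
                 callClass = "unvoiced", seed = sd),
        callSpec(durationS = max(0.2, durs[i]), baseF0 = f0s[i],
                 sweepUp = sweep, sweepFrac = if (sweep > 0) 0.25 else 0,
                 nHarmonics = nH, harmonicAmps = amps,
                 levelDb = levels[i], callClass = "voiced",
                 seed = .perCallSeed(sd, 1)))
    }
    list(class = cls, spec = spec, baseF0 = if (cls == "unvoiced") NA else f0s[i],
         sweepUp = if (cls == "unvoiced") NA else sweep,
         levelDb = levels[i],
         phenomena = if (cls == "voiced" && hasPhen[i]) phenKind[i] else
           character(0))
  })
}

#' Assemble a synthetic session with ground truth
#'
#' Synthesizes every call of a cohort, places the calls at uniformly random
#' non-overlapping onsets separated by at least \code{minGapS}, adds Gaussian
#' background noise at \code{noiseFloorDb}, and returns the recording together
#' with a ground-truth annotation table. Deterministic given the cohort seed.
#'
#' @param cohort a [cohortSpec()].
#' @param sessionLenS session length in seconds (reference sessions are
#'   30 min; tests use shorter ones).
#' @param noiseFloorDb RMS level of the background noise (dB SPL).
#' @param fs sampling rate (Hz, default 44100).
#' @param calibrationDb dB SPL at full-scale RMS.
#' @param minGapS minimum silent gap between consecutive calls (default 0.2).
#' @return list: \code{recording} (a \linkS4class{SessionRecording}),
#'   \code{truth} (data.frame: call_id, onset_s, offset_s, call_class,
#'   base_f0, sweep_up, level_db, phenomena, boundary_s), and \code{f0Funs}
#'   (list of per-call realized F0 contour functions, NULL for unvoiced).
#' @export
assembleSession <- function(cohort, sessionLenS = 60, noiseFloorDb = 40,
                            fs = 44100, calibrationDb = 94, minGapS = 0.2) {
  stopifnot(inherits(cohort, "CohortSpec"))
  entries <- .drawCallSpecs(cohort)
  waves <- vector("list", length(entries))
  f0Funs <- vector("list", length(entries))
  boundaries <- rep(NA_real_, length(entries))
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    if (e$class == "voiced") {
      v <- synthVoicedCall(e$spec, fs, calibrationDb)
      waves[[i]] <- v$wave; f0Funs[[i]] <- v$f0Fun
    } else if (e$class == "unvoiced") {
      waves[[i]] <- synthUnvoicedCall(e$spec$durationS, e$spec$levelDb, fs,
                                      seed = e$spec$seed,
                                      calibrationDb = calibrationDb)
    } else {
      cc <- synthCombinedCall(e$spec, fs, calibrationDb)
      waves[[i]] <- cc$wave; f0Funs[[i]] <- cc$f0Fun
      boundaries[i] <- cc$boundaryS
    }
  }
  durs <- vapply(waves, length, integer(1)) / fs
  n <- length(durs)
  slack <- sessionLenS - sum(durs) - (n + 1) * minGapS
  if (slack < 0)
    stop("calls cannot be packed into the session length", call. = FALSE)

  set.seed(.perCallSeed(cohort$seed, 999983))
  u <- c(0, sort(runif(n)), 1)
  gaps <- diff(u) * slack + minGapS            # n+1 gaps, each >= minGapS
  onsets <- cumsum(gaps[seq_len(n)] + c(0, durs[-n]))

  nTot <- round(sessionLenS * fs)
  sigma <- 10^((noiseFloorDb - calibrationDb) / 20)
  x <- rnorm(nTot, sd = sigma)
  for (i in seq_len(n)) {
    s0 <- round(onsets[i] * fs)
    idx <- (s0 + 1):(s0 + length(waves[[i]]))
    x[idx] <- x[idx] + waves[[i]]
  }
  x <- pmax(-1, pmin(1, x))
  truth <- data.frame(
    call_id = seq_len(n),
    onset_s = onsets,
    offset_s = onsets + durs,
    call_class = vapply(entries, `[[`, character(1), "class"),
    base_f0 = vapply(entries, `[[`, numeric(1), "baseF0"),
    sweep_up = vapply(entries, `[[`, numeric(1), "sweepUp"),
    level_db = vapply(entries, `[[`, numeric(1), "levelDb"),
    phenomena = vapply(entries, function(e)
      paste(e$phenomena, collapse = ";"), character(1)),
    boundary_s = onsets + boundaries,
    stringsAsFactors = FALSE
  )
  ord <- order(truth$onset_s)
  truth <- truth[ord, , drop = FALSE]
  rownames(truth) <- NULL
  rec <- SessionRecording(x, fs, calibrationDb = calibrationDb,
                          group = cohort$group,
                          postnatalDay = .dayForAge(cohort$ageMonths),
                          sessionId = sprintf("synth-%s-%g-%d", cohort$group,
                                              cohort$ageMonths, cohort$seed))
  list(recording = rec, truth = truth, f0Funs = f0Funs[ord])
}

# Representative postnatal day for each age bin (midpoints of the bins).
.dayForAge <- function(ageMonths) {
  switch(as.character(ageMonths),
         "1" = 32L, "1.5" = 39L, "2" = 51L, "3" = 83L,
         stop("unknown age bin"))
}
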