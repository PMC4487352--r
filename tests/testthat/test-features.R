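test_that("constrained autocorrelation recovers a constant F0 within 1%", {
  w <- synthVoicedCall(callSpec(durationS = 0.4, baseF0 = 1000,
                                levelDb = 70, seed = 1), FS)$wave
  fr <- segmentFrames(w, FS)
  tr <- estimateF0Track(w, fr, FS, 1000)
  f0 <- tr@f0Hz[tr@valid]
  expect_gt(length(f0), 30)
  expect_true(all(abs(f0 - 1000) / 1000 < 0.01))

  expect_error(estimateF0Track(w, within(fr, voiced <- FALSE), FS, 1000),
               "no voiced frames")
})

test_that("the +/-30% constraint defines the search band and defeats octave errors", {
  # band arithmetic: expected 1000 -> 700..1300; a 650-Hz call falls outside
  low <- synthVoicedCall(callSpec(durationS = 0.3, baseF0 = 650,
                                  levelDb = 70, seed = 2), FS)$wave
  frL <- segmentFrames(low, FS)
  trL <- estimateF0Track(low, frL, FS, 1000)
  expect_false(any(abs(trL@f0Hz[trL@valid] - 650) / 650 < 0.01))
  # ... but is recovered once the expected F0 matches
  trL2 <- estimateF0Track(low, frL, FS, 650)
  expect_true(all(abs(trL2@f0Hz[trL2@valid] - 650) / 650 < 0.01))

  # adversarial: strong half-F0 components put the global autocorrelation
  # peak at twice the period; the constraint keeps the estimate at F0
  adv <- synthVoicedCall(callSpec(durationS = 0.4, baseF0 = 1000,
                                  harmonicAmps = c(1, 1, 0.5, 0.5, 0.25),
                                  nHarmonics = 5, levelDb = 70,
                                  phenomena = "subharmonic", seed = 3), FS)$wave
  frA <- segmentFrames(adv, FS)
  # wide-band search (expected 650 covers 455-845 Hz) locks onto the
  # subharmonic period -- the documented octave-error risk
  trWide <- estimateF0Track(adv, frA, FS, 650)
  expect_true(any(abs(trWide@f0Hz[trWide@valid] - 500) / 500 < 0.05))
  # constrained search returns the true fundamental
  trC <- estimateF0Track(adv, frA, FS, 1000)
  expect_true(all(abs(trC@f0Hz[trC@valid] - 1000) / 1000 < 0.02))
})

test_that("F1 is found near 2xF0 with sub-bin accuracy and NA propagation", {
  w <- synthVoicedCall(callSpec(durationS = 0.4, baseF0 = 1000,
                                levelDb = 70, seed = 4), FS)$wave
  fr <- segmentFrames(w, FS)
  tr <- estimateF0Track(w, fr, FS, 1000)
  tr@f0Hz[5] <- NA; tr@valid[5] <- FALSE     # simulate an invalid frame
  ft <- estimateF1Track(w, tr, FS)
  expect_true(is.na(ft@f1Hz[5]))
  ok <- ft@valid
  expect_true(all(abs(ft@f1Hz[ok] - 2000) <= FS / 1024))
  expect_true(all(ft@f1Hz[ok] > ft@f0Hz[ok]))
})

test_that("per-call features reduce the tracks correctly", {
  # constant tracks: degenerate statistics
  n <- 20
  tr <- new("ContourTrack", timesS = (1:n - 0.5) / 100,
            f0Hz = rep(1000, n), f1Hz = rep(2000, n), valid = rep(TRUE, n))
  seg <- makeTone(1000, n / 100)
  f <- computeCallFeatures(seg, tr, FS, calibrationDb = 94)
  expect_equal(f$f0_mean, 1000)
  expect_equal(f$f0_max, 1000)
  expect_equal(f$f0_sd, 0)
  expect_equal(f$hr_mean, 2)
  expect_equal(f$hr_max, 2)
  expect_equal(f$hr_at_f0max, 2)

  # full-scale RMS -> level equals the calibration constant
  dc <- rep(c(1, -1), FS / 10)
  trD <- new("ContourTrack", timesS = (1:19 - 0.5) / 100,
             f0Hz = rep(1000, 19), f1Hz = rep(2000, 19),
             valid = rep(TRUE, 19))
  expect_equal(computeCallFeatures(dc, trD, FS, 94)$level_db, 94)

  expect_error(computeCallFeatures(seg, new("ContourTrack",
    timesS = 1:3 / 100, f0Hz = c(1000, NA, NA), f1Hz = rep(NA_real_, 3),
    valid = c(TRUE, FALSE, FALSE)), FS), "fewer than 3")
})

test_that("latency of the F0 maximum matches the programmed sweep", {
  # sweep peaks at sweepFrac * duration / 2 = 0.05 s
  sp <- callSpec(durationS = 0.5, baseF0 = 1000, sweepUp = 200,
                 sweepFrac = 0.2, levelDb = 70, seed = 5)
  w <- synthVoicedCall(sp, FS)$wave
  f <- analyzeCallWave(w, expectedF0MaxHz = 1200)
  expect_lt(abs(f$t_f0max_s - 0.05), 0.010)
  expect_equal(f$f0_max, 1200, tolerance = 0.01)
})

test_that("harmonic-ratio identity holds and phenomena raise its variability", {
  set.seed(19)
  feats <- do.call(rbind, lapply(1:8, function(i) {
    sp <- callSpec(durationS = 0.4, baseF0 = rnorm(1, 1000, 40),
                   levelDb = 70, seed = i)
    analyzeCallWave(synthVoicedCall(sp, FS)$wave)
  }))
  expect_true(all(abs(feats$hr_mean - 2) < 0.05))
  expect_true(all(feats$hr_sd <= 0.05))

  # matched-seed phenomena injection increases hr_sd
  up <- vapply(1:6, function(i) {
    cl <- callSpec(durationS = 0.5, baseF0 = 1000, levelDb = 70, seed = i)
    ph <- callSpec(durationS = 0.5, baseF0 = 1000, levelDb = 70, seed = i,
                   phenomena = "biphonation")
    analyzeCallWave(synthVoicedCall(ph, FS)$wave)$hr_sd >
      analyzeCallWave(synthVoicedCall(cl, FS)$wave)$hr_sd
  }, logical(1))
  expect_gte(mean(up), 5 / 6)
})

test_that("estimated F0 rises monotonically with the programmed F0", {
  f0Levels <- c(800, 900, 1000, 1100, 1200)
  est <- vapply(seq_along(f0Levels), function(i) {
    w <- synthVoicedCall(callSpec(durationS = 0.3, baseF0 = f0Levels[i],
                                  levelDb = 70, seed = i), FS)$wave
    fr <- segmentFrames(w, FS)
    tr <- estimateF0Track(w, fr, FS, f0Levels[i])
    mean(tr@f0Hz[tr@valid])
  }, numeric(1))
  expect_equal(cor(est, f0Levels, method = "spearman"), 1)
})

test_that("analyzeSession produces a coherent per-call table", {
  co <- cohortSpec(callsPerSession = 6, seed = 21)
  ses <- assembleSession(co, sessionLenS = 20, noiseFloorDb = 40)
  feats <- analyzeSession(ses$recording)
  expect_gte(nrow(feats), 5)
  expect_true(all(feats$call_class %in% c("voiced", "unvoiced", "combined")))
  v <- feats$call_class == "voiced"
  expect_true(all(is.finite(feats$f0_mean[v])))
  expect_true(all(is.na(feats$f0_mean[!v])))
  expect_true(all(feats$hr_mean[v] >= 1, na.rm = TRUE))
  expect_true(all(feats$t_f0max_s[v] >= 0 &
                  feats$t_f0max_s[v] <= feats$duration_s[v], na.rm = TRUE))
})
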