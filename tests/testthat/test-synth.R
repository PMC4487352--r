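test_that("F0 contour holds the base frequency and peaks inside the sweep", {
  flat <- makeF0Contour(callSpec(durationS = 0.5, baseF0 = 1000, sweepUp = 0))
  expect_true(all(flat@f0Hz == 1000))

  sw <- makeF0Contour(callSpec(durationS = 0.5, baseF0 = 900, sweepUp = 300,
                               sweepFrac = 0.2))
  expect_equal(max(sw@f0Hz), 1200)
  peakT <- sw@timesS[which.max(sw@f0Hz)]
  expect_gt(peakT, 0)
  expect_lte(peakT, 0.2 * 0.5)
  expect_equal(sum(sw@f0Hz == 1200), 1)     # unique interior maximum
  expect_true(all(sw@f0Hz > 0))
})

test_that("synthesized waveform follows the contour (zero-crossing oracle)", {
  # pure-F0 sinusoid; period re-estimated framewise from zero crossings
  spec <- callSpec(durationS = 0.5, baseF0 = 950, sweepUp = 250,
                   sweepFrac = 0.3, nHarmonics = 1, levelDb = 80)
  v <- synthVoicedCall(spec, FS)
  frameLen <- round(0.010 * FS)
  nf <- floor(length(v$wave) / frameLen)
  for (i in seq(3, nf - 2, by = 4)) {        # skip ramp frames
    x <- v$wave[((i - 1) * frameLen + 1):(i * frameLen)]
    zc <- which(diff(sign(x)) > 0)           # upward crossings
    fZc <- FS * (length(zc) - 1) / (zc[length(zc)] - zc[1])
    fTrue <- v$f0Fun((i - 0.5) * frameLen / FS)
    expect_equal(fZc, fTrue, tolerance = 0.02)
  }
})

test_that("voiced synthesis places harmonic and subharmonic peaks correctly", {
  # pure tone: single dominant spectral peak >= 40 dB above the rest
  tone <- synthVoicedCall(callSpec(durationS = 0.5, baseF0 = 1000,
                                   nHarmonics = 1, levelDb = 70), FS)$wave
  steady <- tone[2206:19845]                 # steady state, past the ramps
  ws <- welchSpectrum(steady, FS)
  iMax <- which.max(ws$power)
  expect_lt(abs(ws$freq_hz[iMax] - 1000), FS / 1024)
  away <- abs(ws$freq_hz - 1000) > 200
  expect_lt(max(ws$power[away]) / ws$power[iMax], 1e-4)   # >= 40 dB down

  # 4-harmonic stack: peaks at k * 1000 Hz
  stack <- synthVoicedCall(callSpec(durationS = 0.5, baseF0 = 1000,
                                    nHarmonics = 4,
                                    harmonicAmps = rep(1, 4),
                                    levelDb = 70), FS)$wave
  pk <- spectralPeaks(welchSpectrum(stack, FS), relFloor = 0.05)
  for (f in c(1000, 2000, 3000, 4000))
    expect_true(any(abs(pk - f) < FS / 1024))

  # subharmonics add interleaved components at 1500 and 2500 Hz
  sub <- synthVoicedCall(callSpec(durationS = 0.6, baseF0 = 1000,
                                  levelDb = 70, phenomena = "subharmonic",
                                  seed = 3), FS)$wave
  pkS <- spectralPeaks(welchSpectrum(sub, FS), relFloor = 5e-4)
  for (f in c(1500, 2500))
    expect_true(any(abs(pkS - f) < FS / 1024))
  # and the clean call has no such peaks
  clean <- synthVoicedCall(callSpec(durationS = 0.6, baseF0 = 1000,
                                    levelDb = 70, seed = 3), FS)$wave
  pkC <- spectralPeaks(welchSpectrum(clean, FS), relFloor = 5e-4)
  expect_false(any(abs(pkC - 1500) < FS / 1024))
})

test_that("synthesis rejects aliasing and wrong call classes", {
  expect_error(synthVoicedCall(callSpec(baseF0 = 5000, nHarmonics = 5), FS),
               "aliasing")
  expect_error(synthVoicedCall(callSpec(callClass = "unvoiced"), FS),
               "not a voiced")
  expect_error(callSpec(durationS = 3), "durationS")
  expect_error(callSpec(sweepFrac = 0.7), "sweepFrac")
  expect_error(callSpec(phenomena = "growl"), "phenomena")
})

test_that("unvoiced calls have exact length and level, and defeat voicing", {
  u <- synthUnvoicedCall(0.3, 70, FS, seed = 5)
  expect_length(u, 13230)
  lvl <- 94 + 20 * log10(sqrt(mean(u^2)))
  expect_equal(lvl, 70, tolerance = 0.1)

  # the voicing classifier should call essentially all purr frames unvoiced
  nVoiced <- 0; nTot <- 0
  for (s in 1:10) {
    fr <- segmentFrames(synthUnvoicedCall(0.5, 70, FS, seed = s), FS)
    nVoiced <- nVoiced + sum(fr$voiced); nTot <- nTot + nrow(fr)
  }
  expect_lt(nVoiced / nTot, 0.01)
})

test_that("combined calls concatenate with a crossfade and a truth boundary", {
  specs <- list(callSpec(durationS = 0.2, callClass = "unvoiced", seed = 1),
                callSpec(durationS = 0.5, baseF0 = 1000, levelDb = 72,
                         seed = 2))
  cc <- synthCombinedCall(specs, FS)
  expect_gte(length(cc$wave) / FS, 0.69)
  expect_lte(length(cc$wave) / FS, 0.70)
  expect_equal(cc$boundaryS, 0.2 - 0.005)   # center of the 10-ms crossfade

  # classifier transition near the truth boundary (+/- 30 ms)
  fr <- segmentFrames(cc$wave, FS)
  flip <- fr$t_center_s[which(fr$voiced)[1]]
  expect_lt(abs(flip - cc$boundaryS), 0.030)
  expect_equal(classifyCall(fr$voiced), "combined")

  expect_error(synthCombinedCall(list(specs[[2]], specs[[2]]), FS),
               "unvoiced part")
})

test_that("session assembly is deterministic, gapped and truthful", {
  co <- cohortSpec(callsPerSession = 12, seed = 77)
  a <- assembleSession(co, sessionLenS = 30)
  b <- assembleSession(co, sessionLenS = 30)
  expect_identical(samples(a$recording), samples(b$recording))
  expect_equal(nrow(a$truth), 12)
  expect_false(is.unsorted(a$truth$onset_s))
  expect_true(all(a$truth$offset_s <= 30))

  # minimum inter-call gap holds across seeds
  for (s in 1:20) {
    tr <- assembleSession(cohortSpec(callsPerSession = 10, seed = s),
                          sessionLenS = 25)$truth
    gaps <- tr$onset_s[-1] - tr$offset_s[-nrow(tr)]
    expect_gte(min(gaps), 0.2)
  }

  # zero calls: pure noise, empty annotations
  z <- assembleSession(cohortSpec(callsPerSession = 0, seed = 1),
                       sessionLenS = 4)
  expect_equal(nrow(z$truth), 0)
  expect_length(samples(z$recording), 4 * FS)

  # impossible packing
  expect_error(assembleSession(cohortSpec(callsPerSession = 40, seed = 1),
                               sessionLenS = 5), "packed")
})

test_that("harmonic-ratio truth: clean calls have F1/F0 = 2 by construction", {
  # by construction of the stack the first harmonic is at exactly 2 x F0;
  # verified on the synthesized spectrum
  w <- synthVoicedCall(callSpec(durationS = 0.4, baseF0 = 1100,
                                levelDb = 70, seed = 9), FS)$wave
  ws <- welchSpectrum(w, FS)
  pk <- spectralPeaks(ws, relFloor = 0.01)
  f0pk <- pk[which.min(abs(pk - 1100))]
  f1pk <- pk[which.min(abs(pk - 2200))]
  expect_equal(f1pk / f0pk, 2, tolerance = 0.02)
})
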