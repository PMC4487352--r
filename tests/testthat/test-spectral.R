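test_that("STFT localizes a tone and has the specified frame count", {
  x <- makeTone(1000, 0.2)
  sp <- stftSpectrogram(x, FS)
  binW <- FS / 1024
  peakF <- spectroFreqs(sp)[apply(spectroPower(sp), 2, which.max)]
  expect_true(all(abs(peakF - 1000) <= binW))

  sp2 <- stftSpectrogram(numeric(4096) + rnorm(4096), FS, win = 1024,
                         overlap = 0.75)
  expect_equal(ncol(spectroPower(sp2)), 1 + (4096 - 1024) %/% 256)

  expect_error(stftSpectrogram(numeric(512), FS), "shorter")
})

test_that("STFT satisfies Parseval's relation per frame", {
  set.seed(2)
  x <- rnorm(2048)
  sp <- stftSpectrogram(x, FS, win = 1024, overlap = 0.75)
  w <- signal::hamming(1024)
  for (j in seq_len(ncol(spectroPower(sp)))) {
    seg <- x[((j - 1) * 256 + 1):((j - 1) * 256 + 1024)] * w
    P <- spectroPower(sp)[, j]
    # one-sided spectrum: double the interior bins, keep DC and Nyquist
    total <- (2 * sum(P) - P[1] - P[length(P)]) / 1024
    expect_equal(total, sum(seg^2), tolerance = 0.01)
  }
})

test_that("average spectrogram is idempotent and onset-aligned", {
  w1 <- synthVoicedCall(callSpec(durationS = 0.4, baseF0 = 1000,
                                 levelDb = 70, seed = 1), FS)$wave
  s1 <- stftSpectrogram(w1, FS)
  avg1 <- averageSpectrogram(list(w1), FS)
  expect_equal(spectroPower(avg1), spectroPower(s1) / max(spectroPower(s1)))

  avg2 <- averageSpectrogram(list(w1, w1), FS)
  expect_equal(spectroPower(avg2), spectroPower(avg1))
  expect_lte(max(spectroPower(avg2)), 1)

  # unequal lengths: frames beyond a short call average only the longer calls
  w2 <- synthVoicedCall(callSpec(durationS = 0.8, baseF0 = 900,
                                 levelDb = 70, seed = 2), FS)$wave
  avgU <- averageSpectrogram(list(w1, w2), FS)
  expect_equal(ncol(spectroPower(avgU)), ncol(spectroPower(stftSpectrogram(w2, FS))))
  expect_error(averageSpectrogram(list(), FS), "no calls")
})

test_that("the average spectrogram shows the onset FM ridge of swept calls", {
  calls <- lapply(1:8, function(i)
    synthVoicedCall(callSpec(durationS = 0.5, baseF0 = 1000, sweepUp = 300,
                             sweepFrac = 0.3, levelDb = 70, seed = i),
                    FS)$wave)
  avg <- averageSpectrogram(calls, FS)
  P <- spectroPower(avg); fr <- spectroFreqs(avg); tt <- spectroTimes(avg)
  band <- fr >= 500 & fr <= 2000         # fundamental region
  domF <- fr[band][apply(P[band, ], 2, which.max)]
  # dominant frequency near the sweep peak early, near the base later
  early <- domF[tt > 0.05 & tt < 0.10]
  late <- domF[tt > 0.35 & tt < 0.45]
  expect_gt(mean(early), mean(late) + 150)
  expect_equal(mean(late), 1000, tolerance = 0.05)
})

test_that("Welch spectra locate harmonic stacks and normalize to 1", {
  ws <- welchSpectrum(makeTone(1000, 0.5), FS)
  expect_equal(max(ws$power), 1)
  expect_lt(abs(ws$freq_hz[which.max(ws$power)] - 1000), FS / 1024)

  stack <- synthVoicedCall(callSpec(durationS = 0.5, baseF0 = 1000,
                                    nHarmonics = 4, harmonicAmps = rep(1, 4),
                                    levelDb = 70), FS)$wave
  pk <- spectralPeaks(welchSpectrum(stack, FS), relFloor = 0.05)
  for (f in 1:4 * 1000) expect_true(any(abs(pk - f) < FS / 1024))

  grp <- averageWelchSpectra(list(stack, stack), FS)
  expect_equal(grp$power, welchSpectrum(stack, FS)$power)
  expect_error(welchSpectrum(numeric(500), FS), "shorter")
})

test_that("cohort Welch peaks track the simulator F0 schedule", {
  peakNear <- function(f0) {
    calls <- lapply(1:5, function(i)
      synthVoicedCall(callSpec(durationS = 0.4, baseF0 = f0, levelDb = 70,
                               seed = i), FS)$wave)
    g <- averageWelchSpectra(calls, FS)
    g$freq_hz[which.max(g$power)]
  }
  p <- vapply(c(1100, 1000, 900, 800), peakNear, numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("5-point median smoothing leaves dominant positions unchanged", {
  for (i in 1:20) {
    set.seed(i)
    sp <- callSpec(durationS = runif(1, 0.2, 0.5), baseF0 = runif(1, 800, 1200),
                   sweepUp = sample(c(0, 250), 1), levelDb = 70, seed = i)
    tf <- tfForTracking(synthVoicedCall(sp, FS)$wave, FS)
    expect_equal(tf@params$argmaxShifted, 0)
  }

  # constant spectrum column is unchanged by the median filter
  flat <- stats::runmed(rep(3, 51), 5)
  expect_true(all(flat == 3))
})
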