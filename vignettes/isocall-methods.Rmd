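---
title: "Methods: automated analysis of kitten isolation calls"
author: "isocall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated analysis of kitten isolation calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The problem

Kittens placed in social isolation emit a voiced vocalization — the isolation
call ("meow") — at high rates: hundreds of calls over a 30-minute session.
The call is a harmonic stack with a fundamental (F0) near 1 kHz, durations of
a few hundred milliseconds up to about 2 s, and, in young animals, a juvenile
up/down frequency-modulated sweep at onset. How the acoustic structure of
this call matures, and how hearing status (normal hearing, mild impairment,
congenital deafness) changes that maturation, is a question about auditory
feedback in a species that is not a classical vocal learner. Answering it at
scale requires an automated pipeline: detecting calls in long recordings,
separating voiced from unvoiced (purr-like) and combined calls, tracking the
fundamental and the first harmonic, and comparing features across groups and
age bins.

`isocall` implements that pipeline, together with a synthetic-call simulator
that provides ground truth, so every stage can be validated quantitatively
without access to animal recordings.

# The analysis chain and its assumptions

## Detection

Sessions are high-pass filtered (Butterworth, 10th order, 500 Hz) to remove
low-frequency energy outside the call band. A 90-ms window slides over the
session in 10-ms steps and the RMS within each window is computed; 130 % of
the session's minimum RMS serves as the detection threshold — the quietest
window is taken as the background-noise reference, so the threshold adapts to
each session's noise floor. Runs of above-threshold windows become call
segments.

Choices behind this stage:

* **Zero-phase filtering.** The filter is applied forward and backward (per
  second-order section), so segment boundaries are not shifted by group
  delay. The 10th-order design is factored into cascaded biquads because a
  single direct-form polynomial at a normalized cutoff of 500/44100 loses its
  stopband to coefficient rounding; the cascade holds the analytic ≥ 120 dB
  zero-phase attenuation one octave below cutoff.
* **Boundary convention.** Segment boundaries are placed at the *centers* of
  the first and last above-threshold RMS windows. At high SNR a window
  barely overlapping a call already crosses the threshold, so edge-of-window
  conventions would bias both boundaries outward by up to a full window;
  the center convention bounds the error by half a window (45 ms).
* **Hop 10 ms** aligns RMS positions with the voicing frames and gives
  sub-window resolution at linear cost. **Merge gap 50 ms** and **minimum
  run 30 ms** curb the splitting of single vocalizations into fragments.
  All are configurable.
* A session containing digital silence (minimum RMS exactly 0) would get a
  useless zero threshold; the smallest positive RMS is used instead, with a
  warning.

## Voicing

Each detected segment is tiled into non-overlapping 10-ms frames. A frame is
voiced when the normalized autocorrelation peak — the maximum over positive
lags in the 400–2000 Hz pitch range, divided by the lag-0 value — exceeds
0.6. Quasi-periodic (glottal) excitation concentrates autocorrelation at the
pitch period; band-limited noise does not. The SIFT (simple inverse filter
tracking) correction then whitens each frame with its own order-12 linear
prediction inverse filter and re-scores the decision on the residual, which
removes the influence of the spectral envelope; a continuity rule flips
isolated single-frame disagreements with both neighbours. If re-scoring
disagrees with the incoming flags on more than half the frames it is treated
as unreliable and the incoming flags are kept — a bounded-intervention
safeguard. A `"smooth"` mode (continuity rule only) is available; re-scoring
plus continuity is the default.

Whole calls are classified from the frame flags: voiced if at least half the
frames are voiced and no unvoiced run of 100 ms or more leads the call;
combined if a leading unvoiced run of at least 100 ms is followed by a voiced
run of at least 100 ms (the purr-onset-then-meow structure); unvoiced
otherwise. The 50 % and 100-ms constants are package conventions.

## F0 and F1 tracking

Per voiced frame, F0 is the sampling rate over the best autocorrelation lag,
with the search restricted to lags whose frequencies lie within ±30 % of the
expected maximum F0 (default 1000 Hz). The constraint is what defeats octave
errors: calls with strong half-F0 components (subharmonics) place the global
autocorrelation maximum at twice the period, and an unconstrained tracker
would halve the pitch. Parabolic interpolation of the autocorrelation peak
gives sub-sample lag resolution (recovery bias on simulated calls is well
under 1 %). Frames whose constrained peak ratio falls below 0.3 are marked
invalid — the automated stand-in for the study-style manual control of
contaminated frames. A two-pass mode re-estimates the expected maximum F0
from the session's median first-pass maximum, which matters for young
cohorts whose onset sweep carries F0 above the default band.

F1 — the first harmonic above the fundamental — is located on a
time–frequency representation (10-ms Hamming windows, 50 % overlap,
zero-padded FFT, 5-point median filter along frequency) as the power maximum
within [1.5, 2.5] × F0, refined by log-power parabolic interpolation on the
unsmoothed spectrum. Searching near, rather than fixing, 2 × F0 is the point:
the harmonic ratio F1/F0 deviates from 2 exactly when phonation is
irregular. Because the spectrogram frames (5-ms hop) need not coincide with
the voicing frame centers, F1 is linearly interpolated between the two
bracketing spectrogram frames; without this, fast onset sweeps (up to
~10 kHz/s) skew F1 against F0 by up to 2 % and inflate the within-call
harmonic-ratio SD in every group.

On the median filter: a 5-point running median flattens an isolated spectral
peak into a short run of tied maxima whose center is the original peak.
Dominant-frequency positions are therefore compared with plateau-aware
tie-breaking, under which the filter provably does not move the energy
maxima on well-formed harmonic frames — the property asserted by
`tfForTracking()` and checked in the tests.

## Per-call features and aggregation

For each voiced call: duration; level
(`calibrationDb + 20·log10(segment RMS)`); mean, maximum and SD of F0; the
latency of the F0 maximum from call onset; and the harmonic-ratio statistics
(mean, SD, maximum, latency of the maximum, and the ratio at the frame of
maximal F0). Statistics use valid frames only; at least 3 are required.

Sessions are summarized by arithmetic means over calls (F0 and
harmonic-ratio features over voiced calls only), plus the percentage of
voiced calls. All group statistics operate on session means — grand means
are means of session means, never call-weighted — matching the aggregation
order of the study design this pipeline reproduces.

## Spectral summaries

Average spectrograms (Hamming window, FFT 1024, 75 % overlap) are built from
voiced calls of 100–1500 ms only: each call's spectrogram is normalized to
its own maximum power, left-aligned at onset, and averaged frame-by-frame
out to the longest call. Shorter calls simply stop contributing (the
denominator varies with frame index); zero-padding them instead would bias
late frames low. Linear power is averaged, and normalization precedes
averaging. Welch spectra (FFT 1024, 50 % overlap) are normalized to maximum
1 per call and then averaged the same way. "Normalized to the maximum" is
interpreted as power normalization; a single constant separates it from
amplitude normalization and the choice does not affect peak positions.

## Statistics

Normality is tested with the Anderson–Darling statistic under Stephens'
small-sample modification (mean and variance estimated), with the pass
decision at α = 0.10; the implementation is direct (the statistic is
defined for samples as small as n = 5, below the n ≥ 8 floor of the
reference implementation, which serves as the cross-check oracle in the
tests). A
Pearson χ² alternative over equiprobable bins is available behind a switch.
Group comparisons pair an F test (larger variance over smaller, two-tailed)
with a two-tailed t test, pooled-variance when the F test does not reject
equality at α = 0.05 and Welch otherwise. No multiple-testing correction is
applied, and non-normal samples are flagged rather than diverted to a
different test. The empirical type-I error of the battery on identical
cohorts is within 5 % ± 3 % (500 replicates in the acceptance tests), and
the normality pass rate on truly normal samples is 90 % ± 3 %.

# The simulator

`callSpec()` / `synthVoicedCall()` generate harmonic stacks whose phase is
the integral of a known F0 contour: an optional raised-sine up/down onset
sweep over the first quarter of the call, then a hold at the base F0.
Defaults: 5 harmonics at −6 dB per harmonic, 10-ms raised-cosine ramps,
levels in dB SPL under a configurable full-scale calibration (94 dB SPL at
RMS 1.0). Unvoiced calls are 0.5–8 kHz noise with 20–30 Hz amplitude
modulation; combined calls crossfade an unvoiced lead into a voiced
continuation over 10 ms. Nonlinear phenomena are injected over a random
interior stretch of the call, as they appear at varying latencies in real
calls: subharmonics as half-integer multiples of F0 at relative amplitude
0.35 (stronger components would push the constrained pitch-lag ratio below
the 0.3 validity floor and the affected frames would be dropped rather than
perturbed); biphonation as a second stack at the incommensurate fundamental
0.77 × F0 at relative amplitude 0.7; frequency jumps as a ×1.2 step in the
contour at a random interior time.

`cohortSpec()` sets the study conditions: the F0-by-age schedule
1100/1000/900/800 Hz at 1/1.5/2/3 months (a simulator convention consistent
with "near 1 kHz" and its developmental decline — not a measured value); an
onset sweep of 300 Hz that shrinks to zero by 3 months in hearing animals;
call durations drawn from a shifted gamma within 0.12–2 s; across-call F0
jitter of 40 Hz; call levels of 70 dB SPL with 3 dB jitter over a 40 dB SPL
noise floor; class mix 86/7/7 % voiced/unvoiced/combined. The deaf preset
adds +10 dB level, keeps the juvenile sweep at all ages, raises the
nonlinear-phenomena probability to 0.30 and the per-call harmonic-amplitude
jitter to 6 dB (hearing 2 dB, impaired 4 dB); the impaired preset lowers the
voiced fraction and widens F0 jitter. Sessions place calls at uniform random
non-overlapping onsets with ≥ 200 ms gaps; a single master seed fans out to
per-call seeds by a fixed counter scheme
(`(seed + 104729·index) mod (2^31 − 1)`), so any call is reproducible in
isolation.

What the simulator does *not* emulate: vocal-tract formants and their
maturation, reverberation and microphone directivity, animal movement
(level changes within a session), overlapping calls, and non-stationary
background noise. Passing the validation suite therefore demonstrates that
the pipeline recovers known structure under controlled conditions — it does
not certify performance on field recordings with those complications.

# Numerical choices and degenerate inputs

* Windows specified in milliseconds are converted to samples by rounding;
  sessions at rates other than 44.1 kHz are accepted without resampling.
* Autocorrelations are computed by FFT; the biased (tapered) estimator is
  used for detection robustness, and peak interpolation runs on the raw
  values around the discrete maximum.
* Zero-energy frames are unvoiced with ratio 0; zero-variance samples fail
  the normality test; sessions with zero calls are excluded from summaries
  with a warning; a threshold computed from a silent session falls back to
  the smallest positive RMS.
* Ties in spectral argmax positions are broken toward the center of the
  maximal plateau (or toward the raw peak when comparing smoothed and raw
  representations).

# Problem sizes in the validation suite

The shipped tests and the acceptance script run the full chain at desk
scale, chosen to keep each property measurable with comfortable margins:
a 120-s detection session with 40 calls; 10,000 voicing frames; 200
F0-recovery calls; 50 matched cohort pairs of 8 calls for the
harmonic-ratio sensitivity test; 100 calls for the median-filter invariance
check; 500 replicates for the statistical calibrations; and a 2-group ×
4-age × 6-session synthetic study (30 calls per 45-s session) for pattern
recovery. Reference sessions at full scale (30 min, 200–600 calls) use the
same code paths.

# Known limitations

* Frames inside a fast onset FM sweep (~10 kHz/s) carry an intrinsic
  harmonic-ratio scatter of roughly 0.5–1 %: the autocorrelation F0 and the
  spectral F1 average the moving frequency over a 10-ms frame with different
  weightings, and the residual mismatch survives the time-interpolation of
  F1. Within-call harmonic-ratio SD is therefore elevated in sweep-heavy
  (young) cohorts for *all* groups, which reduces the contrast between
  groups in those age bins: at desk-scale session counts the deaf-vs-hearing
  difference in harmonic-ratio SD is reliably detected in direction
  everywhere and in pooled-session comparisons, but its per-age-bin
  significance in the youngest bins is power-limited. A related effect: when
  the true F0 exceeds the search band (sweep peak under a low expected F0),
  the two-period autocorrelation peak lies inside the band and yields an
  in-band octave error whose harmonic ratio is still ≈ 2, so it inflates F0
  statistics but barely the harmonic ratio.

* The harmonic-ratio mechanism for subharmonic calls interacts with the F1
  search band: a subharmonic component at exactly 1.5 × F0 sits on the band
  edge and perturbs F1 only when the second harmonic is weak (as under the
  deaf preset's amplitude jitter). The adversarial tests document this
  behaviour.
* Absolute levels are reproducible only up to the session calibration
  constant; no microphone calibration is modelled.
* Biphonation with a second fundamental inside the F0 search band perturbs
  the F0 estimate itself; this is intended (it is the variability mechanism)
  but means phenomena-laden calls do not carry a single well-defined F0.
* The detector assumes a stationary noise floor within a session; slow noise
  drift would shift the single session threshold.
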