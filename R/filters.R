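#' Design a Butterworth high-pass as second-order sections
#'
#' Closed-form design: the analog low-pass prototype poles
#' \eqn{p_k = \exp(i\pi(2k+n-1)/2n)} are transformed to a high-pass at the
#' prewarped cutoff and discretized by the bilinear transform, one conjugate
#' pole pair per biquad. The cascaded form stays numerically accurate at the
#' low normalized cutoffs used here (500 Hz at 44.1 kHz), where a single
#' 10th-order polynomial loses the stopband to coefficient rounding.
#'
#' @param order filter order (even; default 10).
#' @param cutoffHz -3 dB cutoff frequency in Hz.
#' @param fs sampling rate in Hz; must exceed \code{2 * cutoffHz}.
#' @return list of biquads, each a list with numeric \code{b}, \code{a}.
#' @keywords internal
butterHighpassSos <- function(order = 10, cutoffHz = 500, fs = 44100) {
  if (fs <= 2 * cutoffHz)
    stop("sampling rate must exceed twice the cutoff", call. = FALSE)
  if (order < 2 || order %% 2 != 0)
    stop("order must be a positive even integer", call. = FALSE)
  wc <- 2 * fs * tan(pi * cutoffHz / fs)           # prewarped analog cutoff
  k <- seq_len(order)
  pk <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # unit LP prototype
  pHp <- wc / pk                                   # s -> wc/s (high-pass)
  z <- (2 * fs + pHp) / (2 * fs - pHp)             # bilinear; zeros at z = +1
  if (any(Mod(z) >= 1)) stop("unstable design (pathological fs)", call. = FALSE)
  lapply(which(Im(z) > 1e-12), function(i) {
    p <- z[i]
    b <- c(1, -2, 1)
    a <- c(1, -2 * Re(p), Mod(p)^2)
    g <- sum(a * c(1, -1, 1)) / sum(b * c(1, -1, 1))  # unit gain at Nyquist
    list(b = b * g, a = a)
  })
}

#' Zero-phase Butterworth high-pass filter
#'
#' Removes low-frequency energy outside the call band (default: 10th-order
#' Butterworth at 500 Hz). Applied forward-backward per second-order section,
#' so the magnitude response is squared and the phase is zero; call boundaries
#' downstream are not shifted by group delay. The signal is odd-reflection
#' padded at both ends before filtering to suppress edge transients.
#'
#' @param x numeric signal (or a \linkS4class{SessionRecording}).
#' @param fs sampling rate in Hz (ignored when \code{x} is a recording).
#' @param cutoffHz high-pass cutoff (default 500 Hz).
#' @param order Butterworth order (default 10).
#' @return filtered signal of the same length (or a SessionRecording with
#'   filtered samples).
#' @examples
#' t <- (0:4409) / 44100
#' y <- highpassFilter(sin(2 * pi * 5000 * t), 44100)
#' @export
highpassFilter <- function(x, fs, cutoffHz = 500, order = 10) {
  if (is(x, "SessionRecording")) {
    y <- highpassFilter(x@samples, x@fs, cutoffHz, order)
    x@samples <- pmax(-1, pmin(1, y))
    return(x)
  }
  n <- length(x)
  if (n < 4) stop("signal too short to filter", call. = FALSE)
  sos <- butterHighpassSos(order, cutoffHz, fs)
  pad <- min(n - 1, ceiling(3 * fs / cutoffHz))
  xi <- c(2 * x[1] - x[(pad + 1):2],            # odd reflection, left
          x,
          2 * x[n] - x[(n - 1):(n - pad)])      # odd reflection, right
  for (s in sos) {
    xi <- .biquad(xi, s$b, s$a)
    xi <- rev(.biquad(rev(xi), s$b, s$a))      # backward pass: zero phase
  }
  xi[(pad + 1):(pad + n)]
}

# One biquad (direct form): vectorized 3-tap MA, then C-level recursion.
# Poles and zeros stay interleaved section by section, which is what keeps
# the deep stopband of the high-order design within double precision.
.biquad <- function(x, b, a) {
  n <- length(x)
  v <- b[1] * x
  v[2:n] <- v[2:n] + b[2] * x[1:(n - 1)]
  v[3:n] <- v[3:n] + b[3] * x[1:(n - 2)]
  as.numeric(stats::filter(v, -a[2:3], method = "recursive"))
}

#' Band-pass filter helper (Butterworth, zero phase)
#'
#' Used by the simulator to band-limit unvoiced (purr-like) noise. Moderate
#' order, applied with \code{signal::filtfilt}.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param lowHz,highHz band edges (Hz).
#' @param order Butterworth order per passband edge (default 4).
#' @return filtered signal.
#' @keywords internal
bandpassFilter <- function(x, fs, lowHz, highHz, order = 4) {
  stopifnot(lowHz > 0, highHz < fs / 2, lowHz < highHz)
  bf <- signal::butter(order, c(lowHz, highHz) / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}
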