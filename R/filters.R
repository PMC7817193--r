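# Minimal DSP helpers: linear-phase FIR band-pass applied symmetrically
# (zero net phase shift) and an FFT Hilbert envelope. Kept in-package so the
# event detectors have no external signal-processing dependency.

#' Zero-phase FIR band-pass filter
#'
#' Hamming-windowed-sinc FIR applied by centered convolution; the symmetric
#' kernel makes the filter zero-phase, as required for cutting theta cycles
#' at troughs and for ripple envelope timing.
#'
#' @param x signal.
#' @param fs sampling rate, Hz.
#' @param f_lo,f_hi band edges, Hz.
#' @param taps kernel length (odd; default ~3 cycles of `f_lo`).
#' @return filtered signal, same length.
#' @export
fir_bandpass <- function(x, fs, f_lo, f_hi, taps = NULL) {
  stopifnot(f_lo > 0, f_hi > f_lo, f_hi < fs / 2)
  if (is.null(taps)) taps <- round(3 * fs / f_lo)
  if (taps %% 2 == 0) taps <- taps + 1L
  m <- (taps - 1) / 2
  n <- -m:m
  sinc <- function(f) { y <- 2 * f / fs * sin(2 * pi * f / fs * n) / (2 * pi * f / fs * n); y[n == 0] <- 2 * f / fs; y }
  h <- sinc(f_hi) - sinc(f_lo)
  h <- h * (0.54 + 0.46 * cos(pi * n / m))   # Hamming
  conv_same(x, h)
}

#' Instantaneous amplitude envelope via the analytic signal
#' @param x (band-passed) signal.
#' @return non-negative envelope, same length.
#' @export
hilbert_envelope <- function(x) {
  n0 <- length(x)
  n <- stats::nextn(n0, 2)          # pad: keeps the FFT fast at any length
  X <- stats::fft(c(x, rep(0, n - n0)))
  h <- numeric(n)
  h[c(1, n / 2 + 1)] <- 1
  h[2:(n / 2)] <- 2
  env <- Mod(stats::fft(X * h, inverse = TRUE)) / n
  env[seq_len(n0)]
}
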