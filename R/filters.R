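# Zero-phase FIR filtering. Kernels are textbook Hamming-windowed sinc
# designs (ideal band-pass impulse response times a Hamming window), whose
# -6 dB half-amplitude points fall exactly at the requested cutoffs; they
# are applied once by FFT convolution with the group delay of the symmetric
# kernel compensated, so the net response has exactly zero phase without
# squaring the magnitude response.

# ideal low-pass impulse response at normalized cutoff fc = f/rate,
# centered on tap M of 0..order
sinc_lowpass <- function(order, fc) {
  n <- 0:order
  m <- n - order / 2
  h <- 2 * fc * ifelse(m == 0, 1, sin(2 * pi * fc * m) / (2 * pi * fc * m))
  h
}

hamming_window <- function(len) {
  0.54 - 0.46 * cos(2 * pi * (0:(len - 1)) / (len - 1))
}

fft_conv <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nf <- min(stats::nextn(n, 2), stats::nextn(n, c(2, 3)))
  X <- stats::fft(c(x, numeric(nf - length(x))))
  H <- stats::fft(c(h, numeric(nf - length(h))))
  Re(stats::fft(X * H, inverse = TRUE))[seq_len(n)] / nf
}

#' Apply a linear-phase FIR kernel with zero net phase
#'
#' Convolves once and discards the (length-1)/2-sample group delay. The
#' kernel must have odd length (even filter order) so the delay is integer.
#'
#' @param x signal.
#' @param h symmetric FIR kernel, odd length.
#' @return filtered signal, same length as `x` (edges see implicit zero
#'   padding over half a kernel length).
#' @export
apply_fir_zero_phase <- function(x, h) {
  if (length(h) %% 2L != 1L)
    stop("FIR kernel must have odd length (even order)", call. = FALSE)
  d <- (length(h) - 1L) %/% 2L
  y <- fft_conv(as.numeric(x), as.numeric(h))
  y[(d + 1L):(d + length(x))]
}

#' Design a Hamming-windowed sinc band-pass kernel
#'
#' The -6 dB (half-amplitude) points of a windowed-sinc design fall at the
#' requested cutoff frequencies. When `order` is omitted it follows the
#' Hamming design rule `order = 3.3 / (transition / rate)` (rounded up to
#' even), with the transition width taken as the smaller of the two.
#'
#' @param rate sampling rate, Hz.
#' @param low,high -6 dB cutoff frequencies, Hz (0 < low < high < rate/2).
#' @param order FIR order (even); overrides the design rule.
#' @param transition transition width(s) in Hz, length 1 or 2.
#' @return numeric kernel of length `order + 1`.
#' @export
design_bandpass <- function(rate, low, high, order = NULL, transition = 1) {
  nyq <- rate / 2
  if (!(low > 0 && low < high && high < nyq))
    stop(sprintf("band edges must satisfy 0 < %g < %g < %g (Nyquist)",
                 low, high, nyq), call. = FALSE)
  if (is.null(order)) {
    tw <- min(transition)
    order <- ceiling(3.3 * rate / tw)
  }
  order <- as.integer(order) + as.integer(order) %% 2L  # force even
  w <- hamming_window(order + 1L)
  (sinc_lowpass(order, high / rate) - sinc_lowpass(order, low / rate)) * w
}

#' @rdname design_bandpass
#' @param cutoff -6 dB cutoff for the low-pass variant, Hz.
#' @export
design_lowpass <- function(rate, cutoff, order = NULL, transition = 1) {
  nyq <- rate / 2
  if (!(cutoff > 0 && cutoff < nyq))
    stop("cutoff must lie inside (0, Nyquist)", call. = FALSE)
  if (is.null(order)) order <- ceiling(3.3 * rate / min(transition))
  order <- as.integer(order) + as.integer(order) %% 2L
  sinc_lowpass(order, cutoff / rate) * hamming_window(order + 1L)
}

#' Zero-phase band-pass filter
#'
#' Band-passes a signal with a Hamming-windowed sinc FIR whose -6 dB cutoffs
#' sit half a transition width outside the stated passband edges (e.g. a
#' 0.2-35 Hz passband with 0.2 Hz transitions is cut at 0.1 and 35.1 Hz).
#'
#' @param x signal (microvolts).
#' @param rate sampling rate, Hz.
#' @param low,high passband edges, Hz.
#' @param transition transition widths, Hz; length 1 (both sides) or 2
#'   (low side, high side).
#' @param order optional explicit FIR order (even).
#' @return filtered signal, same length.
#' @export
bandpass_zero_phase <- function(x, rate, low, high, transition = c(0.2, 0.2),
                                order = NULL) {
  transition <- rep_len(transition, 2L)
  h <- design_bandpass(rate, low - transition[1] / 2, high + transition[2] / 2,
                       order = order, transition = transition)
  apply_fir_zero_phase(x, h)
}

#' @rdname bandpass_zero_phase
#' @param cutoff low-pass -6 dB cutoff, Hz.
#' @export
lowpass_zero_phase <- function(x, rate, cutoff, transition = 1, order = NULL) {
  h <- design_lowpass(rate, cutoff, order = order, transition = transition)
  apply_fir_zero_phase(x, h)
}

#' Analytic signal via the Hilbert transform
#'
#' Frequency-domain construction: positive frequencies doubled, negative
#' zeroed. The instantaneous phase convention is that of the analytic
#' signal: a cosine has phase 0 at its positive peak, +pi/2 at the falling
#' zero crossing, and +/-pi at the trough.
#'
#' @param x real signal.
#' @return complex analytic signal, same length.
#' @export
hilbert_analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  w <- numeric(n)
  if (n %% 2L == 0L) {
    w[1] <- 1; w[n / 2 + 1] <- 1
    w[2:(n / 2)] <- 2
  } else {
    w[1] <- 1
    w[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * w, inverse = TRUE) / n
}

#' Magnitude (frequency) response of a kernel in dB
#'
#' @param h FIR kernel.
#' @param rate sampling rate, Hz.
#' @param freqs frequencies at which to evaluate, Hz.
#' @return dB magnitude at `freqs` (0 dB = unity gain).
#' @export
fir_response_db <- function(h, rate, freqs) {
  k <- seq_along(h) - 1
  vapply(freqs, function(f) {
    H <- sum(h * exp(-2i * pi * f * k / rate))
    20 * log10(Mod(H))
  }, numeric(1))
}
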