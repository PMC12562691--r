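# Linear-phase FIR design (windowed-sinc, Hamming) and zero-phase application.
#
# Transition bandwidth rule at each edge: min(max(0.25 * edge, 2 Hz), room),
# where "room" is the edge itself at the low side and Nyquist - edge at the
# high side. Filter length is 3.3 / (narrowest transition band), rounded up
# to an odd number of taps, so the kernel is symmetric and the group delay
# integer.

transition_bw <- function(edge, room) {
  min(max(0.25 * edge, 2), room)
}

#' Design a linear-phase FIR band-pass kernel
#'
#' Windowed-sinc design with a Hamming window. The -6 dB cutoffs sit exactly
#' at the requested band edges, with the transition band straddling each
#' edge symmetrically: content half a transition band inside the edge keeps
#' approximately unit gain, content half a transition band outside is in
#' the stop band (about -53 dB for the Hamming window).
#'
#' @param low_hz,high_hz pass-band edges (Hz); `0 < low_hz < high_hz < fs/2`.
#' @param fs sampling rate (Hz).
#' @return Numeric vector of filter taps (odd length, symmetric).
#' @export
fir_bandpass <- function(low_hz, high_hz, fs) {
  nyq <- fs / 2
  if (!(low_hz > 0 && low_hz < high_hz)) {
    stop("band edges must satisfy 0 < low_hz < high_hz", call. = FALSE)
  }
  if (high_hz >= nyq) {
    stop("high_hz must be below the Nyquist frequency ", nyq, " Hz",
         call. = FALSE)
  }
  tb_lo <- transition_bw(low_hz, low_hz)
  tb_hi <- transition_bw(high_hz, nyq - high_hz)
  n_taps <- ceiling(3.3 * fs / min(tb_lo, tb_hi))
  if (n_taps %% 2 == 0) n_taps <- n_taps + 1
  f1 <- low_hz / fs                 # normalized cutoffs (cycles/sample)
  f2 <- high_hz / fs
  m <- seq_len(n_taps) - 1 - (n_taps - 1) / 2
  sinc <- function(t, f) ifelse(t == 0, 2 * f, sin(2 * pi * f * t) / (pi * t))
  h <- sinc(m, f2) - sinc(m, f1)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(n_taps - 1)) / (n_taps - 1))
  h * w
}

# fold arbitrary integer positions into 1..n by reflection (no edge repeat),
# so padding works even when the kernel is longer than the signal
reflect_index <- function(i, n) {
  if (n == 1) return(rep(1L, length(i)))
  period <- 2L * (n - 1L)
  j <- (i - 1L) %% period
  ifelse(j < n, j + 1L, period - j + 1L)
}

# zero-phase application of a symmetric odd-length kernel: reflection-pad,
# FFT convolution, trim at the group delay so net phase shift is zero
apply_fir_vec <- function(x, kernel) {
  n <- length(x)
  p <- (length(kernel) - 1L) / 2L
  xp <- x[reflect_index(seq.int(1L - p, n + p), n)]
  full <- stats::convolve(xp, rev(kernel), type = "open")
  full[(2L * p + 1L):(2L * p + n)]
}

# rows = channels
apply_fir <- function(signal, kernel) {
  if (is.null(dim(signal))) return(apply_fir_vec(signal, kernel))
  t(apply(signal, 1, apply_fir_vec, kernel = kernel))
}
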