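# Broadband filtering, five-band decomposition, sliding-window segmentation.
# Order of operations in the pipeline: resample -> broadband 0.5-100 Hz ->
# band decomposition on the continuous record -> segmentation (pure slicing).

#' Broadband band-pass filter a recording
#'
#' Linear-phase FIR band-pass (default 0.5-100 Hz) applied with group-delay
#' compensation, so the output has zero net phase shift and the same length
#' as the input.
#'
#' @param rec an `eeg_recording`.
#' @param low_hz,high_hz pass-band edges (Hz); `high_hz` must be below
#'   Nyquist.
#' @return Filtered `eeg_recording`.
#' @export
broadband_filter <- function(rec, low_hz = 0.5, high_hz = 100) {
  kern <- fir_bandpass(low_hz, high_hz, rec$fs)
  out <- rec
  out$signal <- apply_fir(rec$signal, kern)
  out
}

#' Decompose a recording into EEG frequency bands
#'
#' One zero-phase FIR band-pass per band; each output has the same shape as
#' the input. Band edges default to the classical five bands of
#' [eeg_bands()]; the 7-8 and 12-13 Hz gaps are preserved.
#'
#' @param rec an `eeg_recording`.
#' @param bands tibble with columns `band`, `low_hz`, `high_hz`.
#' @return Named list of `eeg_recording`s, one per band.
#' @export
decompose_bands <- function(rec, bands = eeg_bands()) {
  nyq <- rec$fs / 2
  if (any(bands$high_hz >= nyq)) {
    stop("band edge at or above Nyquist (", nyq, " Hz)", call. = FALSE)
  }
  out <- purrr::pmap(bands, function(band, low_hz, high_hz) {
    kern <- fir_bandpass(low_hz, high_hz, rec$fs)
    r <- rec
    r$signal <- apply_fir(rec$signal, kern)
    r
  })
  stats::setNames(out, bands$band)
}

#' Segment a recording into sliding windows
#'
#' Windows of `window_s` seconds advanced by `step_s`; trailing samples
#' shorter than a full window are dropped. With the defaults (1 s window,
#' 0.5 s step) windows overlap by 50%.
#'
#' @param rec an `eeg_recording`.
#' @param window_s window length (seconds).
#' @param step_s step between window starts (seconds).
#' @return List with `segments` (array: segments x channels x window
#'   samples), `start_s` (window start times), `window_s`, `step_s`, `fs`.
#' @export
segment_signal <- function(rec, window_s = 1.0, step_s = 0.5) {
  fs <- rec$fs
  win <- round(window_s * fs)
  step <- round(step_s * fs)
  n <- n_samples(rec)
  if (n < win) stop("too short to segment", call. = FALSE)
  n_seg <- floor((n - win) / step) + 1
  starts <- (seq_len(n_seg) - 1) * step
  segs <- array(0, dim = c(n_seg, n_channels(rec), win))
  for (s in seq_len(n_seg)) {
    segs[s, , ] <- rec$signal[, (starts[s] + 1):(starts[s] + win), drop = FALSE]
  }
  list(segments = segs, start_s = starts / fs,
       window_s = window_s, step_s = step_s, fs = fs)
}

#' Number of segments a recording yields
#'
#' @inheritParams segment_signal
#' @return Integer segment count (`floor((samples - window)/step) + 1`).
#' @export
count_segments <- function(rec, window_s = 1.0, step_s = 0.5) {
  win <- round(window_s * rec$fs)
  step <- round(step_s * rec$fs)
  n <- n_samples(rec)
  if (n < win) stop("too short to segment", call. = FALSE)
  as.integer(floor((n - win) / step) + 1)
}

# full per-recording preprocessing: broadband filter, band decomposition,
# segmentation of every band with identical window grid
segment_bands <- function(rec, bands = eeg_bands(), broadband = c(0.5, 100),
                          window_s = 1.0, step_s = 0.5) {
  filtered <- broadband_filter(rec, broadband[1], broadband[2])
  per_band <- decompose_bands(filtered, bands)
  segged <- purrr::map(per_band, segment_signal,
                       window_s = window_s, step_s = step_s)
  list(bands = segged, start_s = segged[[1]]$start_s,
       label = rec$label, recording_id = rec$recording_id)
}
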