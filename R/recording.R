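# The eeg_recording S3 container: channels x samples matrix in microvolts,
# sampling rate, seizure-type label, identifier.

#' Construct an EEG recording
#'
#' @param signal numeric matrix, channels x samples, in microvolts. A vector
#'   is treated as a single channel.
#' @param fs sampling rate in Hz (> 0).
#' @param label seizure-type code (one of [seizure_types()]) or `NA`.
#' @param recording_id identifier string.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(signal, fs, label = NA_character_,
                          recording_id = "rec") {
  if (is.null(dim(signal))) signal <- matrix(signal, nrow = 1)
  stopifnot(is.numeric(signal), fs > 0)
  if (!all(is.finite(signal))) stop("signal must be finite", call. = FALSE)
  if (!is.na(label)) check_labels(label)
  structure(
    list(signal = signal, fs = fs, label = label,
         recording_id = recording_id,
         duration_s = ncol(signal) / fs),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording %s> %d ch x %d samples @ %g Hz (%.2f s), label %s\n",
              x$recording_id, nrow(x$signal), ncol(x$signal), x$fs,
              x$duration_s, x$label))
  invisible(x)
}

#' Number of channels / samples of a recording
#' @param rec an `eeg_recording`.
#' @return integer.
#' @export
n_channels <- function(rec) nrow(rec$signal)

#' @rdname n_channels
#' @export
n_samples <- function(rec) ncol(rec$signal)

#' Corpus tibble from a list of recordings
#'
#' One row per recording with the recording itself in a list-column, so a
#' simulated or loaded corpus pipes straight into [extract_features()].
#'
#' @param recordings list of `eeg_recording` objects.
#' @return Tibble with columns `recording_id`, `label`, `fs`, `duration_s`,
#'   `n_channels`, `recording` (list-column).
#' @export
as_corpus <- function(recordings) {
  tibble::tibble(
    recording_id = vapply(recordings, `[[`, character(1), "recording_id"),
    label        = vapply(recordings, `[[`, character(1), "label"),
    fs           = vapply(recordings, `[[`, numeric(1), "fs"),
    duration_s   = vapply(recordings, `[[`, numeric(1), "duration_s"),
    n_channels   = vapply(recordings, n_channels, integer(1)),
    recording    = recordings
  )
}
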