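# Shared constants and small helpers.

#' Canonical seizure-type codes
#'
#' The six seizure-type labels handled by the package, in the fixed
#' alphabetical order used for confusion matrices and probability columns:
#' ABSZ (absence), CPSZ (complex partial), FNSZ (focal non-specific),
#' GNSZ (generalized non-specific), TCSZ (tonic-clonic), TNSZ (tonic).
#'
#' @return Character vector of length 6.
#' @export
seizure_types <- function() {
  c("ABSZ", "CPSZ", "FNSZ", "GNSZ", "TCSZ", "TNSZ")
}

#' Canonical EEG band definitions
#'
#' The five classical EEG frequency bands with the edges used throughout the
#' package: delta 1-4 Hz, theta 4-7 Hz, alpha 8-12 Hz, beta 13-30 Hz,
#' gamma 30-80 Hz. The 7-8 Hz and 12-13 Hz gaps are intentional and kept
#' as-is; bands are not re-tiled.
#'
#' @return A tibble with columns `band`, `low_hz`, `high_hz`.
#' @export
eeg_bands <- function() {
  tibble::tibble(
    band    = c("delta", "theta", "alpha", "beta", "gamma"),
    low_hz  = c(1, 4, 8, 13, 30),
    high_hz = c(4, 7, 12, 30, 80)
  )
}

#' Canonical per-band feature names
#'
#' The 13 features computed on every band-filtered 1-s segment, in the fixed
#' column order of the feature matrix.
#'
#' @return Character vector of length 13.
#' @export
feature_types <- function() {
  c("mean", "variance", "skewness", "kurtosis", "sample_entropy",
    paste0("wavelet_energy_", 0:4),
    "hurst", "hjorth_mobility", "hjorth_complexity")
}

#' Full 65-column feature-name grid
#'
#' Band-major ordering: all 13 features for delta, then theta, alpha, beta,
#' gamma. Names have the form `"{band}_{feature}"`, e.g.
#' `"gamma_hjorth_complexity"`.
#'
#' @param bands character vector of band names (default all five).
#' @return Character vector of length `13 * length(bands)`.
#' @export
feature_names <- function(bands = eeg_bands()$band) {
  as.vector(vapply(bands, function(b) paste0(b, "_", feature_types()),
                   character(13)))
}

# columns of a feature tibble that are features (not metadata)
feature_columns <- function(fm) {
  intersect(feature_names(), names(fm))
}

# validate a label vector against the canonical codes
check_labels <- function(labels) {
  bad <- setdiff(unique(labels), seizure_types())
  if (length(bad) > 0) {
    stop("unknown seizure-type label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(labels)
}

# population variance (1/N), used by moments and Hjorth
pop_var <- function(x) {
  mean((x - mean(x))^2)
}
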