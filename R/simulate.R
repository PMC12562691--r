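# Synthetic ictal-EEG generator. Each seizure-type profile fixes a relative
# power split over the five EEG bands plus optional periodic spike-wave and
# high-frequency burst components; recordings are sums of band-limited
# Gaussian noise (one filtered-noise component per band), those transients,
# and white sensor noise. Channels share a common term (mixing weight 0.5)
# so inter-channel correlation is nontrivial.

#' Seizure-type simulation profile
#'
#' @param label seizure-type code.
#' @param band_power nonnegative length-5 vector of relative band powers
#'   (delta, theta, alpha, beta, gamma); normalized to sum to 1.
#' @param spike_wave_hz fundamental of a periodic sharpened spike-wave
#'   component (Hz), or `NA` for none.
#' @param burst_rate expected gamma bursts per second.
#' @param amplitude_uv RMS amplitude scale of the composed signal (microvolts).
#' @param noise_sd_uv additive white-noise standard deviation (microvolts).
#' @return An object of class `seizure_profile`.
#' @export
seizure_profile <- function(label, band_power, spike_wave_hz = NA_real_,
                            burst_rate = 0, amplitude_uv = 60,
                            noise_sd_uv = 5) {
  check_labels(label)
  stopifnot(length(band_power) == 5, all(band_power >= 0),
            sum(band_power) > 0, burst_rate >= 0,
            amplitude_uv >= 0, noise_sd_uv >= 0)
  band_power <- band_power / sum(band_power)
  structure(
    list(label = label, band_power = stats::setNames(band_power, eeg_bands()$band),
         spike_wave_hz = spike_wave_hz, burst_rate = burst_rate,
         amplitude_uv = amplitude_uv, noise_sd_uv = noise_sd_uv),
    class = "seizure_profile"
  )
}

#' Default simulation profiles for the six seizure types
#'
#' One profile per code, pairwise distinct in their band-power splits. The
#' absence-type (ABSZ) profile carries the classical 3 Hz spike-wave with
#' delta/theta dominance; the tonic (TNSZ) profile is gamma-dominant
#' (low-voltage fast activity). These are engineered stand-ins that make the
#' six classes separable by the extracted features, not clinically validated
#' electrophysiological templates.
#'
#' @return Named list of 6 `seizure_profile` objects.
#' @export
default_profiles <- function() {
  p <- list(
    seizure_profile("FNSZ", c(0.20, 0.30, 0.25, 0.15, 0.10),
                    spike_wave_hz = NA, burst_rate = 0.2, amplitude_uv = 60),
    seizure_profile("ABSZ", c(0.45, 0.30, 0.10, 0.10, 0.05),
                    spike_wave_hz = 3, burst_rate = 0, amplitude_uv = 80),
    seizure_profile("CPSZ", c(0.20, 0.40, 0.20, 0.12, 0.08),
                    spike_wave_hz = 6, burst_rate = 0.1, amplitude_uv = 70),
    seizure_profile("TCSZ", c(0.15, 0.15, 0.15, 0.30, 0.25),
                    spike_wave_hz = NA, burst_rate = 1.0, amplitude_uv = 100),
    seizure_profile("GNSZ", c(0.32, 0.18, 0.12, 0.26, 0.12),
                    spike_wave_hz = 4, burst_rate = 0.3, amplitude_uv = 75),
    seizure_profile("TNSZ", c(0.05, 0.10, 0.10, 0.25, 0.50),
                    spike_wave_hz = NA, burst_rate = 2.0, amplitude_uv = 50)
  )
  stats::setNames(p, vapply(p, `[[`, character(1), "label"))
}

# one realization of the per-channel process (unit-scale, before RMS scaling)
simulate_process <- function(n, fs, profile) {
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  bands <- eeg_bands()
  for (b in seq_len(nrow(bands))) {
    w <- profile$band_power[[b]]
    if (w <= 0) next
    kern <- fir_bandpass(bands$low_hz[b], bands$high_hz[b], fs)
    comp <- apply_fir_vec(stats::rnorm(n), kern)
    s <- stats::sd(comp)
    if (s > 0) x <- x + sqrt(w) * comp / s
  }
  if (!is.na(profile$spike_wave_hz)) {
    f0 <- profile$spike_wave_hz
    # sawtooth-sharpened sinusoid: decaying harmonic stack
    sw <- sin(2 * pi * f0 * t) + 0.5 * sin(4 * pi * f0 * t) +
      0.25 * sin(6 * pi * f0 * t)
    x <- x + 0.9 * sw / stats::sd(sw)
  }
  if (profile$burst_rate > 0) {
    n_burst <- stats::rpois(1, profile$burst_rate * n / fs)
    if (n_burst > 0) {
      centers <- stats::runif(n_burst, 0, n / fs)
      freqs <- stats::runif(n_burst, 40, 70)
      burst <- numeric(n)
      for (i in seq_len(n_burst)) {
        env <- exp(-((t - centers[i])^2) / (2 * 0.05^2))
        burst <- burst + env * sin(2 * pi * freqs[i] * t)
      }
      x <- x + 1.5 * burst
    }
  }
  x
}

#' Simulate one labeled EEG recording
#'
#' Deterministic for fixed arguments: the RNG is seeded internally, so the
#' same call always returns bit-identical signals.
#'
#' @param profile a `seizure_profile`.
#' @param duration_s duration in seconds (>= 1; shorter cannot be segmented).
#' @param fs sampling rate in Hz (>= 200 so the gamma band fits below Nyquist).
#' @param n_channels number of channels.
#' @param seed integer seed.
#' @param recording_id identifier (defaults to a label/seed-derived string).
#' @return An `eeg_recording`.
#' @export
simulate_recording <- function(profile, duration_s, fs = 250, n_channels = 2,
                               seed = 1,
                               recording_id = sprintf("%s_%06d", profile$label, seed)) {
  if (duration_s < 1) stop("too short to segment", call. = FALSE)
  stopifnot(fs >= 200, n_channels >= 1)
  n <- round(duration_s * fs)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  common <- simulate_process(n, fs, profile)
  sig <- matrix(0, nrow = n_channels, ncol = n)
  for (ch in seq_len(n_channels)) {
    indiv <- simulate_process(n, fs, profile)
    mix <- 0.5 * common + 0.5 * indiv
    rms <- sqrt(mean(mix^2))
    if (rms > 0) mix <- mix * profile$amplitude_uv / rms
    sig[ch, ] <- mix + stats::rnorm(n, sd = profile$noise_sd_uv)
  }
  eeg_recording(sig, fs = fs, label = profile$label,
                recording_id = recording_id)
}

# save/restore global RNG state so simulation is self-seeding but polite
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Per-class recording counts used by the reference corpus
#'
#' The class imbalance of the study corpus: 100 recordings each for the
#' prevalent types (FNSZ, CPSZ, GNSZ), 78 for ABSZ and 47 each for TCSZ and
#' TNSZ — 472 in total.
#'
#' @return Named integer vector.
#' @export
default_corpus_counts <- function() {
  c(FNSZ = 100L, ABSZ = 78L, CPSZ = 100L, TCSZ = 47L, GNSZ = 100L, TNSZ = 47L)
}

#' Simulate a labeled corpus of recordings
#'
#' @param profiles named list of `seizure_profile`s (default
#'   [default_profiles()]).
#' @param counts named integer vector, recordings per class (default
#'   [default_corpus_counts()]).
#' @param duration_range_s length-2 range; durations drawn uniformly.
#' @param fs sampling rate (Hz).
#' @param n_channels channels per recording.
#' @param seed global integer seed; recording i is generated with seed
#'   `seed + i`, so corpora of any size are reproducible.
#' @return A corpus tibble (see [as_corpus()]).
#' @export
simulate_corpus <- function(profiles = default_profiles(),
                            counts = default_corpus_counts(),
                            duration_range_s = c(14.66, 202.68),
                            fs = 250, n_channels = 2, seed = 1) {
  if (length(counts) == 0) stop("counts map must be nonempty", call. = FALSE)
  stopifnot(all(counts >= 1))
  check_labels(names(counts))
  missing <- setdiff(names(counts), names(profiles))
  if (length(missing) > 0) {
    stop("no profile for class(es): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  labels <- rep(names(counts), times = counts)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  durations <- stats::runif(length(labels), duration_range_s[1],
                            duration_range_s[2])
  recs <- purrr::map(seq_along(labels), function(i) {
    simulate_recording(profiles[[labels[i]]], durations[i], fs = fs,
                       n_channels = n_channels, seed = seed + i,
                       recording_id = sprintf("%s_%04d", labels[i], i))
  })
  as_corpus(recs)
}

#' Desk-scale analysis corpus
#'
#' The canonical corpus used by this package's examples and end-to-end
#' checks: the study imbalance pattern scaled to 96 recordings of 12-26 s
#' (roughly 3,300-3,700 one-second segments at the default 0.5 s step).
#'
#' @param seed integer seed.
#' @param n_channels channels per recording.
#' @return A corpus tibble.
#' @export
demo_corpus <- function(seed = 1, n_channels = 2) {
  simulate_corpus(
    counts = c(FNSZ = 20L, ABSZ = 16L, CPSZ = 20L, TCSZ = 10L,
               GNSZ = 20L, TNSZ = 10L),
    duration_range_s = c(12, 26), fs = 250, n_channels = n_channels,
    seed = seed
  )
}
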