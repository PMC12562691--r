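# The 13 per-band segment features and assembly of the 65-column feature
# matrix. All moments are population (1/N) moments; kurtosis is excess
# kurtosis. Degenerate (constant) segments follow fixed conventions so the
# matrix stays free of NaN/Inf: moments (mu, 0, 0, 0), sample entropy 0,
# Hurst 0.5, Hjorth (0, 0).

#' Statistical moments of a window
#'
#' Population mean, variance, skewness and excess kurtosis. A zero-variance
#' window returns skewness and kurtosis 0 by convention.
#'
#' @param x numeric vector, length >= 2.
#' @return Named numeric vector `mean`, `variance`, `skewness`, `kurtosis`.
#' @export
stat_moments <- function(x) {
  if (length(x) < 2) stop("window too short for moments", call. = FALSE)
  mu <- mean(x)
  d <- x - mu
  v <- mean(d^2)
  if (v <= 0) {
    return(c(mean = mu, variance = 0, skewness = 0, kurtosis = 0))
  }
  c(mean = mu, variance = v,
    skewness = mean(d^3) / v^1.5,
    kurtosis = mean(d^4) / v^2 - 3)
}

#' Sample entropy of a window
#'
#' Richman-Moorman sample entropy: the negative log of the conditional
#' probability that template vectors matching for `m` points (Chebyshev
#' distance <= `r`) also match for `m + 1` points, self-matches excluded.
#' The tolerance is `r_factor` times the standard deviation of the window
#' itself. If no (m+1)-length matches exist, the estimate is capped at
#' `log((N - m) * (N - m - 1)) - log(2)`; a constant window returns 0.
#'
#' @param x numeric vector, length > m + 1.
#' @param m embedding dimension (default 2).
#' @param r_factor tolerance multiplier on `sd(x)` (default 0.2).
#' @return Sample entropy in nats (>= 0).
#' @export
sample_entropy <- function(x, m = 2, r_factor = 0.2) {
  n <- length(x)
  if (n <= m + 1) stop("window too short for sample entropy", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) return(0)
  r <- r_factor * s
  nt <- n - m                     # templates for both m and m+1 counts
  # C[i, j] = Chebyshev distance between m-templates starting at i and j
  d <- abs(outer(x, x, "-"))
  cm <- d[seq_len(nt), seq_len(nt)]
  if (m > 1) {
    for (k in seq_len(m - 1)) {
      cm <- pmax(cm, d[seq_len(nt) + k, seq_len(nt) + k])
    }
  }
  b <- sum(cm <= r) - nt          # ordered pairs, self-matches removed
  cm1 <- pmax(cm, d[seq_len(nt) + m, seq_len(nt) + m])
  a <- sum(cm1 <= r) - nt
  if (b == 0) return(0)           # no m-matches: maximal regularity unknown; 0 by convention
  if (a == 0) return(log(nt * (nt - 1)) - log(2))
  -log(a / b)
}

#' Rescaled-range Hurst exponent of a window
#'
#' For each scale `tau` in `2..max_lag` the window is split into
#' `floor(N / tau)` non-overlapping blocks; each block contributes the ratio
#' of the range of its cumulative mean-deviation sums to its sample standard
#' deviation (blocks with zero SD are skipped). The exponent is the
#' least-squares slope of `log(mean R/S)` against `log(tau)`, clipped to
#' [0, 1.5]. A constant window returns 0.5 by convention.
#'
#' @param x numeric vector, length > max_lag.
#' @param max_lag largest block length in samples (default 20).
#' @param min_lag smallest block length (default 2).
#' @return Hurst exponent estimate (unitless).
#' @export
hurst_rs <- function(x, max_lag = 20, min_lag = 2) {
  n <- length(x)
  if (n <= max_lag) stop("window too short for Hurst estimation", call. = FALSE)
  if (stats::sd(x) == 0) return(0.5)
  taus <- seq.int(min_lag, max_lag)
  rs <- vapply(taus, function(tau) {
    nb <- n %/% tau
    m <- matrix(x[seq_len(nb * tau)], nrow = tau)     # columns are blocks
    mc <- m - rep(colMeans(m), each = tau)
    s <- sqrt(colSums(mc^2) / (tau - 1))
    z <- apply(mc, 2, cumsum)
    if (tau == 1) z <- matrix(z, nrow = 1)
    rng <- apply(z, 2, max) - apply(z, 2, min)
    vals <- ifelse(s == 0, NA_real_, rng / s)
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  keep <- is.finite(rs) & rs > 0
  if (sum(keep) < 2) return(0.5)
  h <- stats::coef(stats::lm.fit(cbind(1, log(taus[keep])),
                                 log(rs[keep])))[2]
  min(max(h, 0), 1.5)
}

#' Hjorth mobility and complexity of a window
#'
#' Mobility is `sqrt(Var(diff1) / Var(x))` and complexity is
#' `sqrt(Var(diff2) / Var(diff1)) / mobility`, with `diff1`/`diff2` the
#' first differences of `x` and of `diff1`, and population variances
#' throughout. If `x` or `diff1` has zero variance the affected outputs are
#' 0 by convention.
#'
#' @param x numeric vector, length >= 3.
#' @return Named numeric vector `mobility`, `complexity`.
#' @export
hjorth <- function(x) {
  if (length(x) < 3) stop("window too short for Hjorth parameters",
                          call. = FALSE)
  v0 <- pop_var(x)
  if (v0 == 0) return(c(mobility = 0, complexity = 0))
  d1 <- diff(x)
  v1 <- pop_var(d1)
  mob <- sqrt(v1 / v0)
  if (v1 == 0) return(c(mobility = mob, complexity = 0))
  d2 <- diff(d1)
  v2 <- pop_var(d2)
  comp <- sqrt(v2 / v1) / mob
  c(mobility = mob, complexity = comp)
}

# the 13 features of one band-filtered single-channel window
band_features <- function(x, sampen_m = 2, sampen_r = 0.2,
                          hurst_max_lag = 20,
                          wavelet_mode = "symmetric") {
  c(stat_moments(x),
    sample_entropy = sample_entropy(x, m = sampen_m, r_factor = sampen_r),
    stats::setNames(wavelet_energies(x, mode = wavelet_mode),
                    paste0("wavelet_energy_", 0:4)),
    hurst = hurst_rs(x, max_lag = hurst_max_lag),
    hjorth(x) |> stats::setNames(c("hjorth_mobility", "hjorth_complexity")))
}

#' Extract the multi-band feature matrix from a corpus
#'
#' Runs the full per-recording chain (broadband 0.5-100 Hz filter, band
#' decomposition, sliding-window segmentation) and computes the 13 features
#' per band on every segment. Features are computed per channel and then
#' aggregated across channels (arithmetic mean by default), yielding one
#' row per segment with `13 * n_bands` named feature columns in band-major
#' order plus metadata columns.
#'
#' @param corpus a corpus tibble (see [as_corpus()]) or a single
#'   `eeg_recording`.
#' @param bands band definition tibble; default all five of [eeg_bands()].
#' @param broadband length-2 broadband filter edges (Hz).
#' @param window_s,step_s segmentation window and step (seconds).
#' @param sampen_m,sampen_r sample-entropy embedding dimension and tolerance
#'   factor.
#' @param hurst_max_lag largest R/S block length (samples).
#' @param wavelet_mode db4 boundary mode.
#' @param channel_agg `"mean"`, `"median"`, or `"single:<i>"` to keep one
#'   channel.
#' @return Tibble: one row per segment with columns `recording_id`,
#'   `start_s`, `label`, then the named feature columns.
#' @export
extract_features <- function(corpus, bands = eeg_bands(),
                             broadband = c(0.5, 100),
                             window_s = 1.0, step_s = 0.5,
                             sampen_m = 2, sampen_r = 0.2,
                             hurst_max_lag = 20,
                             wavelet_mode = "symmetric",
                             channel_agg = "mean") {
  if (inherits(corpus, "eeg_recording")) corpus <- as_corpus(list(corpus))
  agg <- channel_aggregator(channel_agg)
  rows <- purrr::map(corpus$recording, function(rec) {
    sb <- segment_bands(rec, bands = bands, broadband = broadband,
                        window_s = window_s, step_s = step_s)
    n_seg <- length(sb$start_s)
    feat <- matrix(NA_real_, nrow = n_seg, ncol = 13 * nrow(bands))
    colnames(feat) <- feature_names(bands$band)
    for (s in seq_len(n_seg)) {
      vals <- purrr::imap(sb$bands, function(bandseg, bname) {
        per_ch <- vapply(seq_len(dim(bandseg$segments)[2]), function(ch) {
          band_features(bandseg$segments[s, ch, ],
                        sampen_m = sampen_m, sampen_r = sampen_r,
                        hurst_max_lag = hurst_max_lag,
                        wavelet_mode = wavelet_mode)
        }, numeric(13))
        agg(per_ch)
      })
      feat[s, ] <- unlist(vals, use.names = FALSE)
    }
    tibble::tibble(recording_id = sb$recording_id, start_s = sb$start_s,
                   label = sb$label) |>
      dplyr::bind_cols(tibble::as_tibble(feat))
  })
  out <- dplyr::bind_rows(rows)
  bad <- !vapply(out[feature_columns(out)],
                 function(col) all(is.finite(col)), logical(1))
  if (any(bad)) {
    stop("non-finite features in column(s): ",
         paste(names(bad)[bad], collapse = ", "), call. = FALSE)
  }
  out
}

# per-channel 13 x n_channels matrix -> length-13 vector
channel_aggregator <- function(channel_agg) {
  if (identical(channel_agg, "mean")) {
    function(m) rowMeans(m)
  } else if (identical(channel_agg, "median")) {
    function(m) apply(m, 1, stats::median)
  } else if (grepl("^single:\\d+$", channel_agg)) {
    ch <- as.integer(sub("^single:", "", channel_agg))
    function(m) m[, ch]
  } else {
    stop("unknown channel aggregation: ", channel_agg, call. = FALSE)
  }
}

#' Standardize feature columns
#'
#' Column-wise z-scoring with parameters fitted on a subset of rows (the
#' training rows in cross-validation) and applied to all rows, so held-out
#' rows are transformed with training statistics only. Columns whose fitted
#' SD is below 1e-12 are set to 0 and flagged.
#'
#' @param fm feature tibble from [extract_features()].
#' @param fit_rows integer indices of the rows used to fit means/SDs
#'   (default all rows).
#' @return List of class `ictal_standardizer` with elements `features`
#'   (transformed tibble), `center`, `scale` (named numeric vectors) and
#'   `constant` (names of degenerate columns).
#' @export
standardize_features <- function(fm, fit_rows = seq_len(nrow(fm))) {
  if (length(fit_rows) == 0) stop("fit_rows must be nonempty", call. = FALSE)
  cols <- feature_columns(fm)
  center <- vapply(fm[fit_rows, cols], mean, numeric(1))
  scale <- vapply(fm[fit_rows, cols], stats::sd, numeric(1))
  constant <- names(scale)[scale < 1e-12]
  out <- fm
  for (cl in cols) {
    if (cl %in% constant) {
      out[[cl]] <- rep(0, nrow(fm))
    } else {
      out[[cl]] <- (fm[[cl]] - center[[cl]]) / scale[[cl]]
    }
  }
  structure(list(features = out, center = center, scale = scale,
                 constant = constant),
            class = "ictal_standardizer")
}

#' Apply fitted standardization parameters to new rows
#'
#' @param std an `ictal_standardizer` from [standardize_features()].
#' @param fm feature tibble with the same feature columns.
#' @return Transformed tibble.
#' @export
apply_standardizer <- function(std, fm) {
  out <- fm
  for (cl in names(std$center)) {
    if (cl %in% std$constant) {
      out[[cl]] <- rep(0, nrow(fm))
    } else {
      out[[cl]] <- (fm[[cl]] - std$center[[cl]]) / std$scale[[cl]]
    }
  }
  out
}
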