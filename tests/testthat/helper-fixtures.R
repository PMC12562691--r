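# Shared fixtures, memoised so expensive corpora are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small 6-class corpus + its feature matrix (for cross-cutting tests)
small_corpus <- function() {
  memo("small_corpus", function() {
    simulate_corpus(
      counts = c(FNSZ = 6L, ABSZ = 5L, CPSZ = 6L, TCSZ = 4L, GNSZ = 6L,
                 TNSZ = 4L),
      duration_range_s = c(8, 14), seed = 3)
  })
}

small_features <- function() {
  memo("small_features", function() extract_features(small_corpus()))
}

# the desk-scale analysis corpus (>= 3000 segments) and its features,
# used by the end-to-end recovery checks
analysis_features <- function() {
  memo("analysis_features", function() extract_features(demo_corpus(seed = 11)))
}

# random feature tibble with the canonical 65 columns: a few columns carry
# class signal, the rest are noise
random_feature_tbl <- function(n = 300, seed = 5, n_classes = 6) {
  set.seed(seed)
  classes <- seizure_types()[seq_len(n_classes)]
  label <- sample(rep_len(classes, n))
  fm <- tibble::tibble(recording_id = sprintf("r%04d", seq_len(n)),
                       start_s = seq_len(n) * 0.5, label = label)
  for (nm in feature_names()) fm[[nm]] <- rnorm(n)
  # plant signal in three columns
  mu <- as.numeric(factor(label, levels = classes))
  fm$gamma_variance <- fm$gamma_variance + 2 * mu
  fm$delta_mean <- fm$delta_mean - mu
  fm$beta_hurst <- fm$beta_hurst + 0.5 * mu^2
  fm
}
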