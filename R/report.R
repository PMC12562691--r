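# Reporting: broom-style accessors for the CV object, ggplot2 heatmaps for
# the pooled confusion matrix and the 5 x 13 MI grid (each with a CSV twin),
# config round-trip, and the end-to-end pipeline driver.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-fold metrics of a cross-validation run
#'
#' @param x an `ictal_cv`.
#' @param ... unused.
#' @return Tibble with one row per model and fold: `model`, `fold`,
#'   `accuracy`, `precision`, `recall`, `f1`, `auc`.
#' @method tidy ictal_cv
#' @export
tidy.ictal_cv <- function(x, ...) {
  purrr::imap_dfr(x$models, function(res, nm) {
    if (isTRUE(res$skipped)) return(tibble::tibble())
    dplyr::mutate(res$fold_metrics, model = nm, .before = 1)
  })
}

#' One-row-per-model summary of a cross-validation run
#'
#' @param x an `ictal_cv`.
#' @param ... unused.
#' @return Tibble with per-model mean and SD of each metric across folds,
#'   the pooled AUC, and elapsed seconds; skipped models appear with
#'   `skipped = TRUE`.
#' @method glance ictal_cv
#' @export
glance.ictal_cv <- function(x, ...) {
  purrr::imap_dfr(x$models, function(res, nm) {
    if (isTRUE(res$skipped)) {
      return(tibble::tibble(model = nm, skipped = TRUE))
    }
    fm <- res$fold_metrics
    tibble::tibble(
      model = nm, skipped = FALSE,
      accuracy = mean(fm$accuracy), accuracy_sd = stats::sd(fm$accuracy),
      precision = mean(fm$precision), recall = mean(fm$recall),
      f1 = mean(fm$f1), f1_sd = stats::sd(fm$f1),
      auc = mean(fm$auc), auc_sd = stats::sd(fm$auc),
      pooled_auc = res$pooled_auc, elapsed_s = res$elapsed_s)
  })
}

#' Confusion-matrix heatmap
#'
#' Log-scaled fill (`log10(count + 1)`), cells annotated `"count (pct%)"`,
#' axes labeled with the class codes; rows are true labels.
#'
#' @param object an `ictal_confusion`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot ictal_confusion
#' @export
autoplot.ictal_confusion <- function(object, ...) {
  if (sum(object$counts) == 0) stop("empty confusion matrix", call. = FALSE)
  df <- confusion_tbl(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$truth,
                                   fill = log10(.data$count + 1))) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d (%.4g%%)",
                                                    .data$count,
                                                    .data$percent)),
                       size = 3) +
    ggplot2::scale_y_discrete(limits = rev(object$classes)) +
    ggplot2::scale_fill_viridis_c(name = "log10(count + 1)") +
    ggplot2::labs(x = "Predicted label", y = "True label") +
    ggplot2::theme_minimal()
}

# long tibble twin of a confusion matrix (percent 0 for empty rows)
confusion_tbl <- function(cm) {
  df <- tidyr::expand_grid(truth = cm$classes, pred = cm$classes)
  df$count <- as.integer(cm$counts[cbind(df$truth, df$pred)])
  pct <- cm$row_percent[cbind(df$truth, df$pred)]
  df$percent <- ifelse(is.na(pct), 0, pct)
  df
}

#' Write a confusion matrix figure with its CSV twins
#'
#' @param cm an `ictal_confusion`.
#' @param out_prefix path prefix; writes `<prefix>.png`,
#'   `<prefix>_counts.csv`, `<prefix>_row_percent.csv`.
#' @return Named character vector of the written paths, invisibly.
#' @export
render_confusion <- function(cm, out_prefix) {
  p <- autoplot(cm)
  paths <- c(png = paste0(out_prefix, ".png"),
             counts = paste0(out_prefix, "_counts.csv"),
             percent = paste0(out_prefix, "_row_percent.csv"))
  ggplot2::ggsave(paths[["png"]], p, width = 7, height = 6, dpi = 150)
  utils::write.csv(cm$counts, paths[["counts"]])
  utils::write.csv(cm$row_percent, paths[["percent"]])
  invisible(paths)
}

#' Band-by-feature MI heatmap
#'
#' The 5 x 13 grid of MI scores: bands (delta..gamma) as rows, the 13
#' feature types as columns, viridis fill, scores printed to three
#' decimals.
#'
#' @param object an `ictal_mi_scores` tibble covering the full 65-name
#'   grid.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot ictal_mi_scores
#' @export
autoplot.ictal_mi_scores <- function(object, ...) {
  missing <- setdiff(feature_names(), object$feature)
  if (length(missing) > 0) {
    stop("missing feature score(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- dplyr::mutate(
    object,
    band = factor(.data$band, levels = rev(eeg_bands()$band)),
    feature_type = factor(.data$feature_type, levels = feature_types()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature_type, y = .data$band,
                                   fill = .data$mi)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$mi)),
                       size = 3, fontface = "bold") +
    ggplot2::scale_fill_viridis_c(name = "MI (nats)") +
    ggplot2::labs(x = "Feature", y = "Band") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Write the MI heatmap with its CSV twin
#'
#' @param scores an `ictal_mi_scores` tibble.
#' @param out_prefix path prefix; writes `<prefix>.png` and
#'   `<prefix>.csv` (5 x 13 wide grid).
#' @return Named character vector of written paths, invisibly.
#' @export
render_mi_heatmap <- function(scores, out_prefix) {
  p <- autoplot(scores)
  wide <- tidyr::pivot_wider(
    dplyr::select(scores, "band", "feature_type", "mi"),
    names_from = "feature_type", values_from = "mi")
  wide <- wide[match(eeg_bands()$band, wide$band),
               c("band", feature_types())]
  paths <- c(png = paste0(out_prefix, ".png"),
             csv = paste0(out_prefix, ".csv"))
  ggplot2::ggsave(paths[["png"]], p, width = 10, height = 4, dpi = 150)
  readr::write_csv(wide, paths[["csv"]])
  invisible(paths)
}

#' Default pipeline configuration
#'
#' Every default is the pipeline's canonical value: 250 Hz working rate,
#' 0.5-100 Hz broadband filter, 1 s windows with 0.5 s step, sample-entropy
#' m = 2 and r = 0.2 sd, Hurst max lag 20, MI top-k 30, 10 folds.
#'
#' @return Named list, YAML-serializable.
#' @export
default_config <- function() {
  list(
    fs = 250, broadband = c(0.5, 100), window_s = 1.0, step_s = 0.5,
    sampen_m = 2, sampen_r = 0.2, hurst_max_lag = 20,
    wavelet_mode = "symmetric", channel_agg = "mean",
    mi_neighbors = 3, selection_k = 30, cv_mode = "fold_wise",
    n_folds = 10, seed = 1, models = c("XGBoost", "Null"),
    simulate = list(n_channels = 2,
                    counts = c(FNSZ = 20, ABSZ = 16, CPSZ = 20, TCSZ = 10,
                               GNSZ = 20, TNSZ = 10),
                    duration_range_s = c(12, 26))
  )
}

#' Load / save a pipeline configuration
#'
#' YAML round-trip; missing keys fall back to [default_config()].
#'
#' @param path YAML file path.
#' @return Config list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_config(), cfg)
}

#' @rdname read_config
#' @param cfg config list.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Run the full pipeline
#'
#' Simulate (or load) a corpus, extract the multi-band feature matrix,
#' score and select features, run cross-validated classification, and write
#' the report artifacts (features TSV, selection JSON, metrics JSON,
#' confusion and MI heatmaps with CSV twins, config and seed log) to a
#' directory.
#'
#' @param cfg configuration list (see [default_config()]).
#' @param out_dir output directory.
#' @param corpus optional pre-built corpus tibble; when `NULL` one is
#'   simulated from `cfg$simulate`.
#' @return The `ictal_cv` result, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(cfg = default_config(), out_dir, corpus = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(corpus)) {
    counts <- unlist(cfg$simulate$counts)
    corpus <- simulate_corpus(
      counts = stats::setNames(as.integer(counts), names(counts)),
      duration_range_s = as.numeric(cfg$simulate$duration_range_s),
      fs = cfg$fs, n_channels = cfg$simulate$n_channels, seed = cfg$seed)
  }
  fm <- extract_features(
    corpus, broadband = as.numeric(cfg$broadband),
    window_s = cfg$window_s, step_s = cfg$step_s,
    sampen_m = cfg$sampen_m, sampen_r = cfg$sampen_r,
    hurst_max_lag = cfg$hurst_max_lag, wavelet_mode = cfg$wavelet_mode,
    channel_agg = cfg$channel_agg)
  readr::write_tsv(fm, file.path(out_dir, "features.tsv"))

  # descriptive global scoring pass (the heatmap is reported regardless of
  # the CV selection mode)
  std <- standardize_features(fm)
  scores <- mi_score_all(std$features, k_neighbors = cfg$mi_neighbors,
                         seed = cfg$seed)
  sel <- select_top_k(scores, k = cfg$selection_k)
  jsonlite::write_json(
    list(k = sel$k, selected = sel$selected,
         scores = as.data.frame(sel$scores)),
    file.path(out_dir, "selection.json"), auto_unbox = TRUE, digits = NA)
  render_mi_heatmap(scores, file.path(out_dir, "mi_heatmap"))

  specs <- purrr::map(cfg$models, model_spec, seed = cfg$seed)
  cv <- run_cv(fm, specs, selection_k = cfg$selection_k,
               cv_mode = cfg$cv_mode, n_folds = cfg$n_folds,
               seed = cfg$seed, mi_neighbors = cfg$mi_neighbors)
  jsonlite::write_json(
    purrr::map(cv$models, function(res) {
      if (isTRUE(res$skipped)) return(list(skipped = TRUE,
                                           message = res$message))
      list(folds = res$fold_metrics,
           mean = as.list(colMeans(res$fold_metrics[-1])),
           sd = purrr::map(res$fold_metrics[-1], stats::sd),
           pooled_auc = res$pooled_auc, elapsed_s = res$elapsed_s)
    }),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  for (nm in names(cv$models)) {
    res <- cv$models[[nm]]
    if (isTRUE(res$skipped)) next
    render_confusion(res$confusion,
                     file.path(out_dir, paste0("confusion_", nm)))
  }
  write_config(cfg, file.path(out_dir, "config.yaml"))
  writeLines(c(paste("seed:", cfg$seed),
               paste("R:", as.character(getRversion())),
               paste("ictalfeat:",
                     as.character(utils::packageVersion("ictalfeat")))),
             file.path(out_dir, "run_log.txt"))
  invisible(cv)
}

#' @importFrom rlang .data
NULL
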