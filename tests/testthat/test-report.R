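test_that("confusion heatmap annotates every cell and matches its CSV twin", {
  set.seed(2)
  truth <- sample(seizure_types(), 120, replace = TRUE)
  pred <- sample(seizure_types(), 120, replace = TRUE)
  cm <- confusion(truth, pred)
  p <- autoplot(cm)
  expect_s3_class(p, "ggplot")
  expect_equal(nrow(p$data), 36)
  expect_true(all(grepl("^\\d+ \\(", sprintf("%d (%.4g%%)", p$data$count,
                                             p$data$percent))))
  td <- withr::local_tempdir()
  paths <- render_confusion(cm, file.path(td, "cm"))
  expect_true(all(file.exists(paths)))
  back <- as.matrix(read.csv(paths[["counts"]], row.names = 1))
  expect_equal(unname(back), unname(cm$counts))
  empty <- confusion(character(0), character(0))
  expect_error(autoplot(empty), "empty")
})

test_that("MI heatmap covers the 5 x 13 grid and round-trips through CSV", {
  fm <- random_feature_tbl(n = 120, seed = 30)
  sc <- mi_score_all(fm, seed = 1)
  p <- autoplot(sc)
  expect_s3_class(p, "ggplot")
  expect_equal(nrow(p$data), 65)
  td <- withr::local_tempdir()
  paths <- render_mi_heatmap(sc, file.path(td, "mi"))
  expect_true(all(file.exists(paths)))
  wide <- readr::read_csv(paths[["csv"]], show_col_types = FALSE)
  expect_equal(dim(wide), c(5, 14))
  expect_equal(wide$band, eeg_bands()$band)
  long <- unlist(wide[wide$band == "gamma", feature_types()])
  expect_equal(unname(long), sc$mi[sc$band == "gamma"])
  # missing names are reported
  expect_error(autoplot(sc[-1, ]), "delta_mean")
})

test_that("config round-trips through YAML with defaults filled in", {
  cfg <- default_config()
  td <- withr::local_tempdir()
  path <- file.path(td, "cfg.yaml")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$window_s, 1.0)
  expect_equal(back$step_s, 0.5)
  expect_equal(back$sampen_m, 2)
  expect_equal(back$sampen_r, 0.2)
  expect_equal(back$hurst_max_lag, 20)
  expect_equal(back$selection_k, 30)
  expect_equal(back$n_folds, 10)
  expect_equal(back$fs, 250)
  expect_equal(as.numeric(back$broadband), c(0.5, 100))
  # partial configs inherit defaults
  writeLines("step_s: 0.2", path)
  part <- read_config(path)
  expect_equal(part$step_s, 0.2)
  expect_equal(part$window_s, 1.0)
})

test_that("the pipeline writes a complete, reproducible report directory", {
  cfg <- default_config()
  cfg$simulate$counts <- c(FNSZ = 4, ABSZ = 3, CPSZ = 4, TCSZ = 3,
                           GNSZ = 4, TNSZ = 3)
  cfg$simulate$duration_range_s <- c(4, 6)
  cfg$n_folds <- 3
  cfg$models <- c("DT", "Null")
  cfg$seed <- 13
  td <- withr::local_tempdir()
  cv <- run_pipeline(cfg, file.path(td, "run1"))
  expect_s3_class(cv, "ictal_cv")
  files <- list.files(file.path(td, "run1"))
  expect_true(all(c("features.tsv", "selection.json", "metrics.json",
                    "mi_heatmap.csv", "mi_heatmap.png", "config.yaml",
                    "run_log.txt", "confusion_DT_counts.csv") %in% files))
  fm <- readr::read_tsv(file.path(td, "run1", "features.tsv"),
                        show_col_types = FALSE)
  expect_length(intersect(names(fm), feature_names()), 65)
  sel <- jsonlite::read_json(file.path(td, "run1", "selection.json"))
  expect_length(sel$selected, 30)
  # deterministic rerun: identical metrics
  cv2 <- run_pipeline(cfg, file.path(td, "run2"))
  expect_equal(glance(cv)$accuracy, glance(cv2)$accuracy, tolerance = 1e-12)
  m1 <- jsonlite::read_json(file.path(td, "run1", "metrics.json"))
  m2 <- jsonlite::read_json(file.path(td, "run2", "metrics.json"))
  drop_time <- function(m) lapply(m, function(x) x[names(x) != "elapsed_s"])
  expect_identical(drop_time(m1), drop_time(m2))
})
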