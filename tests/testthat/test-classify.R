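test_that("balanced class weights follow the inverse-frequency formula", {
  expect_equal(unname(balanced_class_weights(rep(seizure_types(), 10))),
               rep(1, 6))
  w <- balanced_class_weights(rep(c("A", "B"), times = c(90, 10)))
  expect_equal(unname(w), c(100 / (2 * 90), 100 / (2 * 10)),
               tolerance = 1e-12)
  expect_equal(unname(balanced_class_weights(rep("A", 7))), 1)
  expect_error(balanced_class_weights(character(0)), "empty")
})

test_that("SMOTE balances counts with convex, reproducible synthetics", {
  set.seed(8)
  x <- rbind(matrix(rnorm(200, 0), ncol = 2),
             matrix(rnorm(80, 5), ncol = 2))
  y <- rep(c("FNSZ", "ABSZ"), times = c(100, 40))
  out <- smote_oversample(x, y, seed = 4)
  expect_equal(as.integer(table(out$y)[c("FNSZ", "ABSZ")]), c(100, 100))
  # synthetic rows lie inside their class bounding box
  synth <- out$x[141:200, ]
  box <- apply(x[101:140, ], 2, range)
  expect_true(all(synth[, 1] >= box[1, 1] & synth[, 1] <= box[2, 1]))
  expect_true(all(synth[, 2] >= box[1, 2] & synth[, 2] <= box[2, 2]))
  out2 <- smote_oversample(x, y, seed = 4)
  expect_identical(out$x, out2$x)
  expect_error(smote_oversample(rbind(x, c(9, 9)), c(y, "TNSZ")),
               "fewer than 2")
})

test_that("fold plans are stratified partitions", {
  labels <- rep(seizure_types(), each = 100)
  plan <- make_fold_plan(labels, n_folds = 10, seed = 3)
  expect_equal(sort(unique(plan$fold)), 1:10)
  expect_length(plan$fold, 600)
  # each fold holds exactly 10 of each class
  for (cl in seizure_types()) {
    counts <- table(plan$fold[labels == cl])
    expect_true(all(counts == 10))
  }
  # imbalanced labels: per-class fold counts differ by <= 1
  lab2 <- rep(seizure_types(), times = c(78, 100, 100, 100, 47, 47))
  plan2 <- make_fold_plan(lab2, n_folds = 10, seed = 5)
  for (cl in seizure_types()) {
    counts <- tabulate(plan2$fold[lab2 == cl], 10)
    expect_lte(diff(range(counts)), 1)
  }
  expect_false(identical(plan$fold,
                         make_fold_plan(labels, n_folds = 10, seed = 4)$fold))
  expect_error(make_fold_plan(rep(c("ABSZ", "FNSZ"), times = c(5, 100))),
               "ABSZ")
})

test_that("null model predictions are uniform, unit-sum and seeded", {
  pr <- null_model_predict(NULL, 10000, 6, seed = 7)
  expect_equal(dim(pr), c(10000, 6))
  expect_equal(rowSums(pr), rep(1, 10000), tolerance = 1e-12)
  expect_identical(pr, null_model_predict(NULL, 10000, 6, seed = 7))
  # argmax accuracy vs uniform truth ~ 1/6
  set.seed(1)
  truth <- sample(seizure_types(), 10000, replace = TRUE)
  acc <- mean(seizure_types()[max.col(pr)] == truth)
  expect_lt(abs(acc - 1 / 6), 0.015)
})

test_that("cross-validation is deterministic and leakage-safe by fold", {
  fm <- random_feature_tbl(n = 180, seed = 20, n_classes = 3)
  cv1 <- run_cv(fm, model_spec("DT"), n_folds = 3, seed = 6,
                selection_k = 10)
  cv2 <- run_cv(fm, model_spec("DT"), n_folds = 3, seed = 6,
                selection_k = 10)
  expect_identical(cv1$models$DT$prob, cv2$models$DT$prob)
  expect_identical(dplyr::select(glance(cv1), -"elapsed_s"),
                   dplyr::select(glance(cv2), -"elapsed_s"))
  td <- tidy(cv1)
  expect_equal(nrow(td), 3)
  expect_true(all(td$accuracy >= 0 & td$accuracy <= 1))
  # pooled confusion accounts for every segment exactly once
  expect_equal(sum(cv1$models$DT$confusion$counts), nrow(fm))
})

test_that("unavailable model libraries are skipped, the run continues", {
  fm <- random_feature_tbl(n = 90, seed = 21, n_classes = 3)
  expect_warning(
    cv <- run_cv(fm, list(model_spec("LightGBM"), model_spec("Null")),
                 n_folds = 3, seed = 2, selection_k = 5),
    "LightGBM")
  expect_true(cv$models$LightGBM$skipped)
  expect_false(cv$models$Null$skipped)
  g <- glance(cv)
  expect_true(g$skipped[g$model == "LightGBM"])
})

test_that("per-fold selection ignores held-out rows entirely", {
  fm <- random_feature_tbl(n = 240, seed = 22, n_classes = 4)
  plan <- make_fold_plan(fm$label, n_folds = 4, seed = 9)
  cv1 <- run_cv(fm, model_spec("Null"), plan = plan, selection_k = 10,
                seed = 9)
  # plant an extreme outlier column touching only fold 1's held-out rows
  fm2 <- fm
  held <- plan$fold == 1
  fm2$theta_kurtosis[held] <- fm2$theta_kurtosis[held] + 1e6
  cv2 <- run_cv(fm2, model_spec("Null"), plan = plan, selection_k = 10,
                seed = 9)
  expect_identical(cv1$models$Null$selections[[1]],
                   cv2$models$Null$selections[[1]])
})

test_that("paper-compat mode selects once, globally", {
  fm <- random_feature_tbl(n = 120, seed = 23, n_classes = 3)
  cv <- run_cv(fm, model_spec("Null"), n_folds = 3, seed = 2,
               selection_k = 8, cv_mode = "paper_compat")
  sels <- cv$models$Null$selections
  expect_true(all(vapply(sels, identical, logical(1), sels[[1]])))
})

test_that("model specs carry the documented default strategies", {
  expect_equal(model_spec("SVM")$imbalance_strategy, "class_weight_balanced")
  expect_equal(model_spec("KNN")$imbalance_strategy, "smote")
  expect_equal(model_spec("XGBoost")$imbalance_strategy,
               "inverse_freq_sample_weight")
  expect_equal(model_spec("CatBoost")$imbalance_strategy, "auto_balanced")
  expect_equal(model_spec("Null")$imbalance_strategy, "none")
  expect_error(model_spec("AdaBoost"), "unknown model")
})
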