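test_that("confusion counting and row percentages are exact", {
  cm <- confusion(c("ABSZ", "ABSZ", "CPSZ", "CPSZ"),
                  c("ABSZ", "CPSZ", "CPSZ", "CPSZ"),
                  class_order = c("ABSZ", "CPSZ"))
  expect_equal(unname(cm$counts), rbind(c(1, 1), c(0, 2)))
  expect_equal(unname(cm$row_percent), rbind(c(50, 50), c(0, 100)))
  perfect <- confusion(seizure_types(), seizure_types())
  expect_equal(unname(diag(perfect$counts)), rep(1L, 6))
  expect_equal(unname(diag(perfect$row_percent)), rep(100, 6))
  # empty class row: percentages NA, never NaN-propagating
  cm2 <- confusion(c("ABSZ", "ABSZ"), c("ABSZ", "CPSZ"),
                   class_order = c("ABSZ", "CPSZ"))
  expect_true(all(is.na(cm2$row_percent["CPSZ", ])))
  expect_equal(sum(cm2$row_percent["ABSZ", ]), 100)
  expect_error(confusion("XYZ", "ABSZ"), "outside class order")
})

test_that("weighted metrics match hand evaluation", {
  cm <- confusion(c("ABSZ", "ABSZ", "CPSZ", "CPSZ"),
                  c("ABSZ", "CPSZ", "CPSZ", "CPSZ"),
                  class_order = c("ABSZ", "CPSZ"))
  wm <- weighted_metrics(cm)
  expect_equal(wm[["precision"]], 0.5 * 1 + 0.5 * (2 / 3))
  expect_equal(wm[["recall"]], 0.75)
  expect_equal(wm[["f1"]], 0.5 * (2 / 3) + 0.5 * 0.8)
  expect_equal(accuracy(cm), 0.75)
  perfect <- confusion(seizure_types(), seizure_types())
  expect_equal(unname(weighted_metrics(perfect)), c(1, 1, 1))
})

test_that("weighted recall equals accuracy on random fixtures", {
  for (s in 1:20) {
    set.seed(s)
    truth <- sample(seizure_types(), 200, replace = TRUE)
    pred <- sample(seizure_types(), 200, replace = TRUE)
    cm <- confusion(truth, pred)
    expect_equal(weighted_metrics(cm)[["recall"]], accuracy(cm),
                 tolerance = 1e-12)
  }
})

test_that("class relabeling leaves weighted aggregates unchanged", {
  set.seed(5)
  truth <- sample(seizure_types(), 300, replace = TRUE)
  pred <- sample(seizure_types(), 300, replace = TRUE)
  perm <- setNames(seizure_types()[c(3, 1, 6, 2, 4, 5)], seizure_types())
  wm1 <- weighted_metrics(confusion(truth, pred))
  wm2 <- weighted_metrics(confusion(unname(perm[truth]),
                                    unname(perm[pred])))
  expect_equal(wm1, wm2, tolerance = 1e-12)
})

test_that("binary AUC hand fixtures and tie conventions hold", {
  classes <- c("ABSZ", "CPSZ")
  truth <- c("CPSZ", "CPSZ", "ABSZ", "ABSZ")
  p_pos <- c(0.9, 0.8, 0.3, 0.2)
  prob <- cbind(ABSZ = 1 - p_pos, CPSZ = p_pos)
  expect_equal(multiclass_auc(truth, prob, classes), 1)
  p_swap <- c(0.9, 0.3, 0.8, 0.2)
  prob2 <- cbind(ABSZ = 1 - p_swap, CPSZ = p_swap)
  expect_equal(multiclass_auc(truth, prob2, classes), 0.75)
  # one-hot truth -> AUC 1
  lab <- sample(seizure_types(), 50, replace = TRUE)
  onehot <- outer(lab, seizure_types(), "==") * 1
  expect_equal(multiclass_auc(lab, onehot), 1)
  # constant probability column for a present class -> 0.5 via midranks
  const <- matrix(1 / 6, nrow = 50, ncol = 6)
  expect_equal(multiclass_auc(lab, const), 0.5)
  expect_error(multiclass_auc(lab, onehot * 2), "sum to 1")
})

test_that("rank-statistic AUC equals trapezoidal ROC integration", {
  for (s in 1:20) {
    set.seed(s)
    n <- 80
    truth <- sample(c("ABSZ", "FNSZ"), n, replace = TRUE)
    p <- runif(n)
    p <- round(p, 1)                      # force ties
    prob <- cbind(ABSZ = 1 - p, FNSZ = p)
    mine <- multiclass_auc(truth, prob, c("ABSZ", "FNSZ"))
    pos <- truth == "FNSZ"
    n_pos <- sum(pos)
    oracle <- (n_pos * trapezoid_auc(pos, p) +
                 (n - n_pos) * trapezoid_auc(!pos, 1 - p)) / n
    expect_equal(mine, oracle, tolerance = 1e-12)
  }
})

test_that("rank-statistic AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  truth <- sample(c("ABSZ", "FNSZ"), 200, replace = TRUE)
  p <- runif(200)
  prob <- cbind(ABSZ = 1 - p, FNSZ = p)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = p, levels = c("ABSZ", "FNSZ"),
    direction = "<", quiet = TRUE)))
  # both class columns carry the same binary information here
  expect_equal(multiclass_auc(truth, prob, c("ABSZ", "FNSZ")), ref,
               tolerance = 1e-12)
})
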