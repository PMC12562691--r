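# Cross-validated seizure-type classification. Classifier internals are
# delegated to established libraries (e1071, rpart, ranger, xgboost); this
# module owns the fold plan, per-fold standardization and MI selection, the
# imbalance strategies, and the aggregation of held-out predictions.

#' Classifier specification
#'
#' Fixes the wrapped learner, its imbalance strategy and seed. Default
#' strategies: SVM/DT/RF/LightGBM use balanced class weights, KNN uses
#' fold-wise SMOTE, XGBoost uses inverse-class-frequency sample weights
#' with a multiclass soft-probability objective, CatBoost auto-balanced
#' weights, the null model none.
#'
#' @param name one of `"SVM"`, `"KNN"`, `"DT"`, `"RF"`, `"LightGBM"`,
#'   `"CatBoost"`, `"XGBoost"`, `"Null"`.
#' @param imbalance_strategy override of the default strategy.
#' @param hyper named list of hyperparameter overrides for the wrapped
#'   learner.
#' @param seed integer seed for the learner.
#' @return Object of class `ictal_model_spec`.
#' @export
model_spec <- function(name,
                       imbalance_strategy = NULL,
                       hyper = list(), seed = 1) {
  known <- c("SVM", "KNN", "DT", "RF", "LightGBM", "CatBoost", "XGBoost",
             "Null")
  idx <- match(toupper(name), toupper(known))
  if (is.na(idx)) stop("unknown model: ", name, call. = FALSE)
  name <- known[idx]
  defaults <- c(SVM = "class_weight_balanced", KNN = "smote",
                DT = "class_weight_balanced", RF = "class_weight_balanced",
                LightGBM = "class_weight_balanced",
                CatBoost = "auto_balanced",
                XGBoost = "inverse_freq_sample_weight", Null = "none")
  if (is.null(imbalance_strategy)) imbalance_strategy <- defaults[[name]]
  structure(list(name = name, imbalance_strategy = imbalance_strategy,
                 hyper = hyper, seed = seed),
            class = "ictal_model_spec")
}

#' Balanced class weights
#'
#' `weight_c = n_total / (n_classes * n_c)`, so a perfectly balanced label
#' set gets unit weights everywhere.
#'
#' @param labels label vector.
#' @return Named numeric vector of per-class weights.
#' @export
balanced_class_weights <- function(labels) {
  if (length(labels) == 0) stop("empty labels", call. = FALSE)
  counts <- table(labels)
  w <- length(labels) / (length(counts) * as.numeric(counts))
  stats::setNames(w, names(counts))
}

#' SMOTE oversampling
#'
#' Upsamples every minority class to the majority count with synthetic rows
#' `x_i + u * (x_nn - x_i)`, `u ~ U[0, 1)`, where `x_nn` is one of the
#' `k_neighbors` same-class nearest neighbours of a randomly chosen seed
#' row. Deterministic under `seed`. Intended for training rows only.
#'
#' @param x numeric feature matrix (rows = segments).
#' @param y labels, one per row.
#' @param k_neighbors neighbours considered per seed row (default 5).
#' @param seed integer seed.
#' @return List with upsampled `x` and `y`.
#' @export
smote_oversample <- function(x, y, k_neighbors = 5, seed = 1) {
  x <- as.matrix(x)
  counts <- table(y)
  if (any(counts < 2)) {
    stop("class '", names(counts)[which.min(counts)],
         "' has fewer than 2 members; reduce k or exclude it",
         call. = FALSE)
  }
  target <- max(counts)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  new_x <- list()
  new_y <- list()
  for (cl in names(counts)) {
    need <- target - counts[[cl]]
    if (need == 0) next
    rows <- which(y == cl)
    cx <- x[rows, , drop = FALSE]
    k <- min(k_neighbors, nrow(cx) - 1)
    d2 <- as.matrix(stats::dist(cx))^2
    diag(d2) <- Inf
    nn <- t(apply(d2, 1, function(dd) order(dd)[seq_len(k)]))
    seeds <- sample(nrow(cx), need, replace = TRUE)
    picks <- nn[cbind(seeds, sample(k, need, replace = TRUE))]
    u <- stats::runif(need)
    synth <- cx[seeds, , drop = FALSE] +
      u * (cx[picks, , drop = FALSE] - cx[seeds, , drop = FALSE])
    new_x[[cl]] <- synth
    new_y[[cl]] <- rep(cl, need)
  }
  list(x = rbind(x, do.call(rbind, new_x)),
       y = c(as.character(y), unlist(new_y, use.names = FALSE)))
}

#' Stratified fold plan
#'
#' Seeded, shuffled assignment of segments to folds with per-class counts
#' differing by at most one across folds.
#'
#' @param labels label vector, every class with at least `n_folds` members.
#' @param n_folds number of folds (default 10).
#' @param seed integer seed.
#' @return Object of class `ictal_fold_plan`: list with integer `fold`
#'   (1..n_folds per segment), `n_folds`, `seed`.
#' @export
make_fold_plan <- function(labels, n_folds = 10, seed = 1) {
  counts <- table(labels)
  small <- names(counts)[counts < n_folds]
  if (length(small) > 0) {
    stop("class(es) with fewer members than folds: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in names(counts)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(sample(n_folds), length(idx))
  }
  structure(list(fold = fold, n_folds = n_folds, seed = seed),
            class = "ictal_fold_plan")
}

#' Null-model probability predictions
#'
#' Uniform Dirichlet(1, ..., 1) probability vectors per test segment: a
#' feature-free baseline whose expected accuracy is `1/n_classes` and whose
#' expected one-vs-rest AUC is 0.5.
#'
#' @param labels_train training labels (unused by the uniform null; kept so
#'   all predictors share a signature).
#' @param n_test number of test rows.
#' @param n_classes number of classes (>= 2).
#' @param seed integer seed.
#' @return `n_test` x `n_classes` probability matrix with unit row sums.
#' @export
null_model_predict <- function(labels_train, n_test, n_classes, seed = 1) {
  stopifnot(n_classes >= 2)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  g <- matrix(stats::rexp(n_test * n_classes), nrow = n_test)
  g / rowSums(g)
}

# ---- wrapped learners ----------------------------------------------------
# each fitter returns list(predict = function(newx) prob matrix with one
# column per level of `levels`)

require_pkg <- function(pkg, model) {
  if (!requireNamespace(pkg, quietly = TRUE)) {
    stop(errorCondition(
      paste0("model ", model, " requires package '", pkg,
             "', which is not installed"),
      class = c("ictal_model_unavailable", "error")))
  }
}

fit_model <- function(spec, x, y, levels, fold_seed) {
  w_class <- balanced_class_weights(y)
  w_sample <- as.numeric(w_class[y])
  switch(
    spec$name,
    SVM = {
      require_pkg("e1071", "SVM")
      fit <- e1071::svm(x = x, y = factor(y, levels = levels),
                        kernel = "radial", probability = TRUE,
                        class.weights = w_class)
      list(predict = function(newx) {
        pr <- attr(stats::predict(fit, newx, probability = TRUE),
                   "probabilities")
        pr[, levels, drop = FALSE]
      })
    },
    KNN = {
      k <- spec$hyper$k %||% 5
      train_x <- x
      train_y <- y
      list(predict = function(newx) {
        knn_prob(train_x, train_y, newx, k = k, levels = levels)
      })
    },
    DT = {
      require_pkg("rpart", "DT")
      df <- data.frame(.y = factor(y, levels = levels), x)
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          weights = w_sample)
      list(predict = function(newx) {
        pr <- stats::predict(fit, data.frame(newx), type = "prob")
        pad_prob(pr, levels)
      })
    },
    RF = {
      require_pkg("ranger", "RF")
      df <- data.frame(.y = factor(y, levels = levels), x)
      fit <- ranger::ranger(.y ~ ., data = df, probability = TRUE,
                            num.trees = spec$hyper$num.trees %||% 300,
                            case.weights = w_sample, seed = fold_seed,
                            num.threads = 1)
      list(predict = function(newx) {
        pr <- stats::predict(fit, data.frame(newx),
                             num.threads = 1)$predictions
        pad_prob(pr, levels)
      })
    },
    XGBoost = {
      require_pkg("xgboost", "XGBoost")
      yi <- match(y, levels) - 1
      dtrain <- xgboost::xgb.DMatrix(x, label = yi, weight = w_sample)
      fit <- xgboost::xgb.train(
        params = list(objective = "multi:softprob",
                      num_class = length(levels),
                      eta = spec$hyper$eta %||% 0.3,
                      max_depth = spec$hyper$max_depth %||% 6,
                      nthread = 1, seed = fold_seed),
        data = dtrain, nrounds = spec$hyper$nrounds %||% 80, verbose = 0)
      list(predict = function(newx) {
        pr <- stats::predict(fit, xgboost::xgb.DMatrix(newx))
        if (is.null(dim(pr))) {
          pr <- matrix(pr, ncol = length(levels), byrow = TRUE)
        }
        colnames(pr) <- levels
        pr
      })
    },
    LightGBM = stop(errorCondition(
      "model LightGBM requires package 'lightgbm', which is not installed",
      class = c("ictal_model_unavailable", "error"))),
    CatBoost = stop(errorCondition(
      "model CatBoost requires package 'catboost', which is not installed",
      class = c("ictal_model_unavailable", "error"))),
    Null = {
      n_train <- length(y)
      list(predict = function(newx) {
        pr <- null_model_predict(y, nrow(newx), length(levels),
                                 seed = fold_seed)
        colnames(pr) <- levels
        pr
      })
    },
    stop("unknown model: ", spec$name, call. = FALSE)
  )
}

# Euclidean k-NN class-probability predictor (vote shares among the k
# nearest training rows)
knn_prob <- function(train_x, train_y, newx, k, levels) {
  newx <- as.matrix(newx)
  d2 <- outer(rowSums(newx^2), rowSums(train_x^2), "+") -
    2 * newx %*% t(train_x)
  pr <- matrix(0, nrow = nrow(newx), ncol = length(levels),
               dimnames = list(NULL, levels))
  for (i in seq_len(nrow(newx))) {
    nn <- order(d2[i, ])[seq_len(k)]
    tab <- table(factor(train_y[nn], levels = levels))
    pr[i, ] <- as.numeric(tab) / k
  }
  pr
}

# ensure a probability matrix has one column per level, zeros for absentees
pad_prob <- function(pr, levels) {
  out <- matrix(0, nrow = nrow(pr), ncol = length(levels),
                dimnames = list(NULL, levels))
  out[, colnames(pr)] <- pr
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- cross-validation driver --------------------------------------------

#' Cross-validated training and evaluation
#'
#' For each fold: fit the standardizer and MI selection on the training
#' rows (default `cv_mode = "fold_wise"`, leakage-safe; `"paper_compat"`
#' standardizes and selects once globally before folding), apply the
#' spec's imbalance strategy to the training rows only, fit the wrapped
#' learner, and collect held-out class-probability predictions. Per-fold
#' metrics are aggregated to mean and SD; pooled predictions yield the
#' confusion matrix.
#'
#' Models whose wrapped library is unavailable are recorded as skipped
#' (with the error message) and the run continues.
#'
#' @param fm feature tibble from [extract_features()] (unstandardized).
#' @param specs list of [model_spec()]s (a single spec is accepted).
#' @param plan an [make_fold_plan()] plan, or `NULL` to build one from
#'   `n_folds` and `seed`.
#' @param selection_k number of MI-selected features (default 30); `NULL`
#'   or `Inf` disables selection.
#' @param cv_mode `"fold_wise"` or `"paper_compat"`.
#' @param n_folds,seed used when `plan` is `NULL`.
#' @param mi_neighbors neighbours for the MI estimator.
#' @return Object of class `ictal_cv`; see [tidy.ictal_cv()] and
#'   [glance.ictal_cv()].
#' @export
run_cv <- function(fm, specs, plan = NULL, selection_k = 30,
                   cv_mode = c("fold_wise", "paper_compat"),
                   n_folds = 10, seed = 1, mi_neighbors = 3) {
  cv_mode <- match.arg(cv_mode)
  if (inherits(specs, "ictal_model_spec")) specs <- list(specs)
  levels <- intersect(seizure_types(), unique(fm$label))
  if (is.null(plan)) plan <- make_fold_plan(fm$label, n_folds, seed)
  stopifnot(length(plan$fold) == nrow(fm))
  no_select <- is.null(selection_k) || !is.finite(selection_k)

  if (cv_mode == "paper_compat") {
    global_std <- standardize_features(fm)
    fm_g <- global_std$features
    if (!no_select) {
      sel_g <- select_top_k(mi_score_all(fm_g, k_neighbors = mi_neighbors,
                                         seed = seed), k = selection_k)
    }
  }

  results <- list()
  for (spec in specs) {
    res <- tryCatch(
      run_cv_one(spec, fm, plan, levels, selection_k, cv_mode,
                 if (cv_mode == "paper_compat") fm_g else NULL,
                 if (cv_mode == "paper_compat" && !no_select) sel_g else NULL,
                 mi_neighbors, seed),
      ictal_model_unavailable = function(e) {
        warning("skipping ", spec$name, ": ", conditionMessage(e),
                call. = FALSE)
        list(skipped = TRUE, message = conditionMessage(e))
      })
    results[[spec$name]] <- res
  }
  structure(list(models = results, plan = plan, levels = levels,
                 cv_mode = cv_mode, selection_k = selection_k, seed = seed),
            class = "ictal_cv")
}

run_cv_one <- function(spec, fm, plan, levels, selection_k, cv_mode,
                       fm_global, sel_global, mi_neighbors, seed) {
  n <- nrow(fm)
  no_select <- is.null(selection_k) || !is.finite(selection_k)
  prob <- matrix(NA_real_, nrow = n, ncol = length(levels),
                 dimnames = list(NULL, levels))
  fold_rows <- list()
  selections <- list()
  t0 <- proc.time()[["elapsed"]]
  for (f in seq_len(plan$n_folds)) {
    test <- which(plan$fold == f)
    train <- which(plan$fold != f)
    if (cv_mode == "fold_wise") {
      std <- standardize_features(fm, fit_rows = train)
      fmt <- std$features
      if (!no_select) {
        sel <- select_top_k(
          mi_score_all(fmt[train, ], k_neighbors = mi_neighbors,
                       seed = seed),
          k = selection_k)
        keep <- sel$selected
      } else keep <- feature_columns(fmt)
    } else {
      fmt <- fm_global
      keep <- if (no_select) feature_columns(fmt) else sel_global$selected
    }
    selections[[f]] <- keep
    x_train <- as.matrix(fmt[train, keep])
    y_train <- fm$label[train]
    x_test <- as.matrix(fmt[test, keep])
    fold_seed <- spec$seed * 1000 + f
    if (spec$imbalance_strategy == "smote") {
      sm <- smote_oversample(x_train, y_train,
                             k_neighbors = spec$hyper$smote_k %||% 5,
                             seed = fold_seed)
      x_train <- sm$x
      y_train <- sm$y
    }
    fit <- fit_model(spec, x_train, y_train, levels, fold_seed)
    pr <- fit$predict(x_test)[, levels, drop = FALSE]
    prob[test, ] <- pr / rowSums(pr)   # learners emit float32 rounding
    fold_rows[[f]] <- test
  }
  elapsed <- proc.time()[["elapsed"]] - t0
  pred <- levels[max.col(prob, ties.method = "first")]
  fold_metrics <- purrr::map_dfr(seq_len(plan$n_folds), function(f) {
    idx <- fold_rows[[f]]
    cm <- confusion(fm$label[idx], pred[idx], levels)
    wm <- weighted_metrics(cm)
    tibble::tibble(fold = f, accuracy = accuracy(cm),
                   precision = wm[["precision"]], recall = wm[["recall"]],
                   f1 = wm[["f1"]],
                   auc = multiclass_auc(fm$label[idx],
                                        prob[idx, , drop = FALSE], levels))
  })
  pooled_cm <- confusion(fm$label, pred, levels)
  list(skipped = FALSE, spec = spec, fold_metrics = fold_metrics,
       prob = prob, pred = pred, truth = fm$label,
       confusion = pooled_cm,
       pooled_auc = multiclass_auc(fm$label, prob, levels),
       selections = selections, elapsed_s = elapsed)
}

#' @export
print.ictal_cv <- function(x, ...) {
  cat("<ictal_cv>", length(x$models), "model(s),", x$plan$n_folds,
      "folds, mode", x$cv_mode, "\n")
  print(generics::glance(x))
  invisible(x)
}
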