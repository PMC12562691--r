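# Multiclass evaluation: confusion-matrix accounting, support-weighted
# one-vs-rest precision/recall/F1, and weighted one-vs-rest ROC AUC
# computed from the midrank statistic. Zero-division conventions: a class
# with no predicted positives gets precision 0; a constant probability
# column for a class present in the truth gets AUC 0.5.

#' Confusion matrix with row percentages
#'
#' Rows are true classes, columns predicted, in the fixed alphabetical class
#' order. Row percentages are counts over row sums times 100; rows with
#' zero support are left at `NA` rather than NaN.
#'
#' @param truth,pred label vectors of equal length.
#' @param class_order class codes fixing the row/column order.
#' @return Object of class `ictal_confusion`: list with integer `counts`,
#'   `row_percent`, and `classes`.
#' @export
confusion <- function(truth, pred, class_order = seizure_types()) {
  stopifnot(length(truth) == length(pred))
  bad <- setdiff(unique(c(truth, pred)), class_order)
  if (length(bad) > 0) {
    stop("label(s) outside class order: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tt <- factor(truth, levels = class_order)
  pp <- factor(pred, levels = class_order)
  counts <- unclass(table(truth = tt, pred = pp))
  rs <- rowSums(counts)
  pct <- counts * NA_real_
  nz <- rs > 0
  pct[nz, ] <- counts[nz, , drop = FALSE] / rs[nz] * 100
  structure(list(counts = counts, row_percent = pct, classes = class_order),
            class = "ictal_confusion")
}

#' @export
print.ictal_confusion <- function(x, ...) {
  cat("<ictal_confusion>", sum(x$counts), "pooled predictions\n")
  print(x$counts)
  invisible(x)
}

#' Support-weighted precision, recall and F1 from a confusion matrix
#'
#' Per-class one-vs-rest precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and
#' their harmonic mean, averaged with class-support weights. A class with
#' no predicted positives contributes precision 0; a class with zero
#' support is excluded (weight 0).
#'
#' @param cm an `ictal_confusion`.
#' @return Named numeric vector `precision`, `recall`, `f1` (all weighted).
#' @export
weighted_metrics <- function(cm) {
  counts <- cm$counts
  total <- sum(counts)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  tp <- diag(counts)
  support <- rowSums(counts)
  predicted <- colSums(counts)
  prec <- ifelse(predicted > 0, tp / predicted, 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  w <- support / total
  c(precision = sum(w * prec), recall = sum(w * rec), f1 = sum(w * f1))
}

#' Overall accuracy from a confusion matrix
#'
#' @param cm an `ictal_confusion`.
#' @return Proportion of correct classifications (trace over total).
#' @export
accuracy <- function(cm) {
  sum(diag(cm$counts)) / sum(cm$counts)
}

# binary ROC AUC via the midrank (Mann-Whitney) statistic
binary_auc <- function(pos, score) {
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)                      # midranks handle ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Weighted one-vs-rest multiclass AUC
#'
#' Per class, the binary ROC AUC of that class's probability column against
#' the one-vs-rest truth, computed with the rank statistic (midranks for
#' ties, so a constant column for a present class scores 0.5). Classes
#' absent from the truth are excluded and the support weights renormalized.
#'
#' @param truth label vector.
#' @param prob matrix of class probabilities, one column per class in
#'   `class_order`; rows must sum to 1 (tolerance 1e-6).
#' @param class_order class codes fixing the column order.
#' @return Weighted one-vs-rest AUC in [0, 1].
#' @export
multiclass_auc <- function(truth, prob, class_order = seizure_types()) {
  prob <- as.matrix(prob)
  stopifnot(length(truth) == nrow(prob), ncol(prob) == length(class_order))
  if (any(abs(rowSums(prob) - 1) > 1e-6)) {
    stop("probability rows must sum to 1", call. = FALSE)
  }
  support <- vapply(class_order, function(cl) sum(truth == cl), numeric(1))
  aucs <- vapply(seq_along(class_order), function(j) {
    if (support[j] == 0) return(NA_real_)
    binary_auc(truth == class_order[j], prob[, j])
  }, numeric(1))
  present <- !is.na(aucs)
  sum(aucs[present] * support[present]) / sum(support[present])
}
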