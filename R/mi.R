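# Mutual information between continuous features and discrete class labels,
# estimated with the nearest-neighbour method for mixed variables:
#   I(X;Y) = psi(N) - <psi(N_y)> + psi(k) - <psi(m_i)>
# where for each point i, d_i is the Chebyshev distance to its k-th nearest
# neighbour within the same class and m_i counts all points (any class,
# self included) strictly closer than d_i. Negative estimates are clipped
# to zero.

# k-th nearest same-class neighbour distance and m_i counts, 1-D, exact.
# xs must be the full sorted sample; implemented with windowed search so the
# whole scoring pass is O(n k + n log n) per feature.
knn_mi_single <- function(x, y, k) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]
  ys <- y[ord]
  d_i <- numeric(n)
  for (cl in unique(ys)) {
    pos <- which(ys == cl)
    cx <- xs[pos]
    m <- length(cx)
    for (j in seq_len(m)) {
      lo <- max(1, j - k)
      hi <- min(m, j + k)
      cand <- abs(cx[c(lo:hi)[-(j - lo + 1)]] - cx[j])
      d_i[pos[j]] <- sort(cand, partial = k)[k]
    }
  }
  # m_i: points strictly inside (x_i - d_i, x_i + d_i); binary search on xs
  left <- findInterval(xs - d_i, xs)                    # count <= x_i - d_i
  right <- findInterval(xs + d_i, xs, left.open = TRUE) # count <  x_i + d_i
  m_i <- right - left
  n_y <- table(ys)[as.character(ys)]
  mi <- digamma(n) - mean(digamma(as.numeric(n_y))) +
    digamma(k) - mean(digamma(m_i))
  max(mi, 0)
}

#' Mutual information between one continuous feature and class labels
#'
#' Nearest-neighbour estimator for a continuous variable against a discrete
#' label, in nats. A tiny seeded Gaussian jitter (SD
#' `1e-10 * max(1, mean(|x|))`) breaks ties deterministically; a constant
#' feature returns 0.
#'
#' @param x numeric feature values, one per segment.
#' @param y class labels (>= 2 distinct classes, each with at least
#'   `k_neighbors + 1` members).
#' @param k_neighbors number of same-class neighbours (default 3).
#' @param seed integer seed for the tie-breaking jitter.
#' @return MI estimate in nats (>= 0).
#' @export
mi_continuous_discrete <- function(x, y, k_neighbors = 3, seed = 1) {
  stopifnot(length(x) == length(y))
  y <- as.character(y)
  if (length(unique(y)) < 2) {
    stop("labels must contain at least two classes", call. = FALSE)
  }
  counts <- table(y)
  if (any(counts < k_neighbors + 1)) {
    stop("every class needs more than k_neighbors members", call. = FALSE)
  }
  if (stats::sd(x) == 0) return(0)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  x <- x + stats::rnorm(length(x), sd = 1e-10 * max(1, mean(abs(x))))
  knn_mi_single(x, y, k_neighbors)
}

#' Score every feature column against the segment labels
#'
#' One MI estimate per feature column. The jitter RNG is reseeded
#' identically for each column, so duplicated columns receive identical
#' scores and the whole pass is reproducible.
#'
#' @param fm feature tibble with a `label` column.
#' @param k_neighbors same-class neighbour count.
#' @param seed integer seed.
#' @return Tibble of class `ictal_mi_scores` with columns `feature`, `band`,
#'   `feature_type`, `mi` (nats), sorted in canonical feature order;
#'   attributes `k_neighbors` and `seed`.
#' @export
mi_score_all <- function(fm, k_neighbors = 3, seed = 1) {
  cols <- feature_columns(fm)
  if (length(cols) == 0) stop("no feature columns found", call. = FALSE)
  scores <- vapply(cols, function(cl) {
    mi_continuous_discrete(fm[[cl]], fm$label, k_neighbors = k_neighbors,
                           seed = seed)
  }, numeric(1))
  bands <- eeg_bands()$band
  band_of <- function(nm) bands[vapply(bands, function(b)
    startsWith(nm, paste0(b, "_")), logical(1))][1]
  out <- tibble::tibble(
    feature = cols,
    band = vapply(cols, band_of, character(1)),
    feature_type = mapply(function(nm, b) sub(paste0("^", b, "_"), "", nm),
                          cols, vapply(cols, band_of, character(1))),
    mi = unname(scores)
  )
  structure(out, class = c("ictal_mi_scores", class(out)),
            k_neighbors = k_neighbors, seed = seed)
}

#' Retain the top-k features by MI score
#'
#' Descending sort by score with ties broken by ascending feature name, so
#' selection is deterministic.
#'
#' @param scores an `ictal_mi_scores` tibble (or any tibble with `feature`
#'   and `mi` columns).
#' @param k number of features to keep (default 30).
#' @return List of class `ictal_selection` with `selected` (ordered names),
#'   `k`, and the full `scores` tibble.
#' @export
select_top_k <- function(scores, k = 30) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  ord <- order(-scores$mi, scores$feature)
  sel <- scores$feature[ord][seq_len(min(k, nrow(scores)))]
  structure(list(selected = sel, k = k, scores = scores),
            class = "ictal_selection")
}

#' @export
print.ictal_selection <- function(x, ...) {
  cat("<ictal_selection> top", length(x$selected), "of", nrow(x$scores),
      "features by mutual information\n")
  cat(strwrap(paste(x$selected, collapse = ", "), width = 76,
              prefix = "  "), sep = "\n")
  invisible(x)
}
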