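# Independent brute-force oracles. These deliberately use plain nested
# loops / direct definitions and share no code with the package internals.

# sample entropy by direct template counting (Chebyshev distance,
# self-matches excluded, both counts over N - m templates)
brute_sampen <- function(x, m = 2, r_factor = 0.2) {
  n <- length(x)
  s <- sd(x)
  if (s == 0) return(0)
  r <- r_factor * s
  nt <- n - m
  a <- 0L
  b <- 0L
  for (i in seq_len(nt)) {
    for (j in seq_len(nt)) {
      if (i == j) next
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        b <- b + 1L
        if (abs(x[i + m] - x[j + m]) <= r) a <- a + 1L
      }
    }
  }
  if (b == 0) return(0)
  if (a == 0) return(log(nt * (nt - 1)) - log(2))
  -log(a / b)
}

# rescaled-range Hurst exponent by direct block loops
brute_hurst <- function(x, max_lag = 20, min_lag = 2) {
  n <- length(x)
  if (sd(x) == 0) return(0.5)
  taus <- min_lag:max_lag
  log_rs <- numeric(0)
  log_tau <- numeric(0)
  for (tau in taus) {
    nb <- floor(n / tau)
    vals <- c()
    for (b in seq_len(nb)) {
      seg <- x[((b - 1) * tau + 1):(b * tau)]
      s <- sd(seg)
      if (s == 0) next
      z <- cumsum(seg - mean(seg))
      vals <- c(vals, (max(z) - min(z)) / s)
    }
    if (length(vals) > 0 && mean(vals) > 0) {
      log_rs <- c(log_rs, log(mean(vals)))
      log_tau <- c(log_tau, log(tau))
    }
  }
  if (length(log_rs) < 2) return(0.5)
  h <- coef(lm(log_rs ~ log_tau))[[2]]
  min(max(h, 0), 1.5)
}

# exact plug-in mutual information (nats) from the empirical joint table
plugin_mi <- function(x, y) {
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p)
  py <- colSums(p)
  mi <- 0
  for (i in seq_along(px)) {
    for (j in seq_along(py)) {
      if (p[i, j] > 0) mi <- mi + p[i, j] * log(p[i, j] / (px[i] * py[j]))
    }
  }
  unname(mi)
}

# binary ROC AUC by explicit trapezoidal integration of the ROC curve
trapezoid_auc <- function(pos, score) {
  thr <- c(Inf, sort(unique(score), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) mean(score[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(score[!pos] >= t), numeric(1))
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}
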