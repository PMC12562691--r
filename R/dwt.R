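# Daubechies-4 (db4, 8-tap) discrete wavelet transform, decomposition only.
# Two boundary modes: "symmetric" (half-point reflection padding; default)
# and "periodization" (circular; orthonormal for even lengths, so energy is
# conserved exactly). Conventions match the standard pyramid algorithm:
# convolve with the decomposition filters and keep every second coefficient.

# db4 decomposition low-pass filter (reversed scaling coefficients)
db4_dec_lo <- c(-0.010597401785069032, 0.0328830116668852,
                0.030841381835560764, -0.18703481171909309,
                -0.027983769416859854, 0.6308807679298589,
                0.7148465705529157, 0.2303778133088965)

# quadrature-mirror high-pass: g[k] = (-1)^(k+1) * h[F-1-k] (0-based)
db4_dec_hi <- rev(db4_dec_lo) * rep(c(-1, 1), 4)

# symmetric (whole-sample-repeated) index fold for padding
symmetric_index <- function(i, n) {
  j <- (i - 1L) %% (2L * n)
  ifelse(j < n, j + 1L, 2L * n - j)
}

dwt_step_symmetric <- function(x, flt) {
  n <- length(x)
  f <- length(flt)
  pad <- x[symmetric_index(seq.int(1L - (f - 1L), n + f - 1L), n)]
  v <- stats::convolve(pad, rev(flt), type = "open")
  v <- v[f:(length(v) - f + 1L)]          # 'valid' part, length n + f - 1
  v[seq.int(2L, length(v), by = 2L)]
}

dwt_step_periodization <- function(x, flt) {
  if (length(x) %% 2L == 1L) x <- c(x, x[length(x)])
  n <- length(x)
  f <- length(flt)
  half <- f %/% 2L
  out <- numeric(n %/% 2L)
  for (i in seq_along(out)) {
    idx <- (2L * (i - 1L) + half - (0:(f - 1L))) %% n + 1L
    out[i] <- sum(flt * x[idx])
  }
  out
}

dwt_step <- function(x, flt, mode) {
  switch(mode,
         symmetric = dwt_step_symmetric(x, flt),
         periodization = dwt_step_periodization(x, flt),
         stop("unknown wavelet boundary mode: ", mode, call. = FALSE))
}

#' Multilevel db4 wavelet decomposition
#'
#' @param x numeric vector (length >= 16 for the default 4 levels).
#' @param level number of decomposition levels.
#' @param mode boundary mode, `"symmetric"` (default) or `"periodization"`.
#' @return Named list `cA<level>`, `cD<level>`, ..., `cD1` (coarse to fine),
#'   as coefficient vectors.
#' @export
dwt_db4 <- function(x, level = 4, mode = c("symmetric", "periodization")) {
  mode <- match.arg(mode)
  if (length(x) < 2^level) {
    stop("signal too short for a ", level, "-level decomposition",
         call. = FALSE)
  }
  details <- vector("list", level)
  approx <- x
  for (l in seq_len(level)) {
    details[[l]] <- dwt_step(approx, db4_dec_hi, mode)
    approx <- dwt_step(approx, db4_dec_lo, mode)
  }
  out <- c(list(approx), rev(details))
  stats::setNames(out, c(paste0("cA", level),
                         paste0("cD", seq(level, 1))))
}

#' Wavelet sub-band energies of a segment
#'
#' Energies of the five coefficient sets of a 4-level db4 decomposition:
#' E0 is the energy (sum of squared coefficients) of the level-4
#' approximation, E1..E4 the energies of the detail coefficients from
#' level 4 (coarsest) down to level 1 (finest).
#'
#' @param x numeric vector, length >= 16.
#' @param mode boundary mode passed to [dwt_db4()].
#' @return Named numeric vector `E0`..`E4`.
#' @export
wavelet_energies <- function(x, mode = c("symmetric", "periodization")) {
  mode <- match.arg(mode)
  if (length(x) < 16) stop("segment too short for 4-level db4", call. = FALSE)
  coefs <- dwt_db4(x, level = 4, mode = mode)
  stats::setNames(vapply(coefs, function(cc) sum(cc^2), numeric(1)),
                  paste0("E", 0:4))
}
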