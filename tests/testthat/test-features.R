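test_that("moments match hand-evaluated values and conventions", {
  expect_equal(stat_moments(c(1, 2, 3, 4)),
               c(mean = 2.5, variance = 1.25, skewness = 0,
                 kurtosis = -1.36))
  expect_equal(stat_moments(rep(5, 4)),
               c(mean = 5, variance = 0, skewness = 0, kurtosis = 0))
  # symmetric sample -> exactly zero skewness
  x <- c(-3, -1, 0, 1, 3)
  expect_equal(stat_moments(x)[["skewness"]], 0, tolerance = 1e-12)
  expect_error(stat_moments(1), "too short")
})

test_that("moments of Gaussian draws approach Gaussian values", {
  set.seed(42)
  m <- stat_moments(rnorm(1e5))
  expect_equal(m[["skewness"]], 0, tolerance = 0.05)
  expect_equal(m[["kurtosis"]], 0, tolerance = 0.1)
})

test_that("moment scaling behaviour is correct", {
  set.seed(7)
  x <- rnorm(500)
  a <- 3.7
  m1 <- stat_moments(x)
  m2 <- stat_moments(a * x)
  expect_equal(m2[["mean"]], a * m1[["mean"]])
  expect_equal(m2[["variance"]], a^2 * m1[["variance"]])
  expect_equal(m2[["skewness"]], m1[["skewness"]])
  expect_equal(m2[["kurtosis"]], m1[["kurtosis"]])
})

test_that("sample entropy follows the template-matching conventions", {
  expect_equal(sample_entropy(rep(2, 50)), 0)
  expect_equal(sample_entropy(rep(c(1, -1), 125)), 0)
  expect_error(sample_entropy(c(1, 2, 3), m = 2), "too short")
})

test_that("sample entropy equals the brute-force oracle exactly", {
  for (s in 1:50) {
    set.seed(s)
    x <- runif(250)
    expect_equal(sample_entropy(x), brute_sampen(x), tolerance = 1e-12)
  }
  # scale invariance: r tracks the SD of the window
  set.seed(99)
  x <- rnorm(250)
  expect_equal(sample_entropy(17 * x), sample_entropy(x), tolerance = 1e-12)
})

test_that("wavelet energies match the reference transform", {
  # frozen oracle values computed with an independent db4 implementation
  # (PyWavelets 1.9.0) on sin(2*pi*t/7) + 0.05*t, t = 0..63
  x <- sin(2 * pi * (0:63) / 7) + 0.05 * (0:63)
  expect_equal(unname(wavelet_energies(x, "symmetric")),
               c(318.395550627980, 0.322114140069, 12.284815548671,
                 25.509650129570, 0.925974098577), tolerance = 1e-10)
  expect_equal(unname(wavelet_energies(x, "periodization")),
               c(201.077643382299, 4.239670917036, 8.475041804728,
                 21.982651112513, 2.543950384222), tolerance = 1e-10)
})

test_that("wavelet energy behaves as an orthonormal decomposition", {
  expect_equal(unname(wavelet_energies(rep(0, 64))), rep(0, 5))
  # unit impulse under periodization: total energy conserved
  imp <- c(1, rep(0, 15))
  expect_equal(sum(wavelet_energies(imp, "periodization")), 1,
               tolerance = 1e-10)
  # energy conservation for lengths divisible by 16
  for (n in c(64, 160, 256)) {
    set.seed(n)
    x <- rnorm(n)
    expect_equal(sum(wavelet_energies(x, "periodization")), sum(x^2),
                 tolerance = 1e-8)
  }
  # slow 2 Hz tone concentrates in the approximation band
  t <- (0:249) / 250
  e <- wavelet_energies(sin(2 * pi * 2 * t))
  expect_true(all(e[["E0"]] > e[2:5]))
  expect_error(wavelet_energies(rnorm(10)), "too short")
})

test_that("Hurst estimator equals the brute-force oracle exactly", {
  for (s in 1:50) {
    set.seed(s)
    x <- rnorm(250)
    expect_equal(hurst_rs(x), brute_hurst(x), tolerance = 1e-12)
  }
  expect_equal(hurst_rs(rep(3, 100)), 0.5)
  expect_error(hurst_rs(rnorm(15), max_lag = 20), "too short")
})

test_that("integrated noise is more persistent than the noise itself", {
  wins <- 0
  for (s in 1:20) {
    set.seed(200 + s)
    w <- rnorm(250)
    wins <- wins + (hurst_rs(cumsum(w)) > hurst_rs(w))
  }
  expect_gte(wins, 18)
})

test_that("Hjorth parameters match closed forms", {
  expect_equal(hjorth(rep(1, 10)), c(mobility = 0, complexity = 0))
  # sampled sinusoid: Var(diff)/Var(x) = 4 sin^2(pi f / fs)
  t <- (0:249) / 250
  h <- hjorth(sin(2 * pi * 10 * t))
  expect_lt(abs(h[["mobility"]] - 2 * sin(pi * 10 / 250)), 1e-3)
  expect_lt(abs(h[["complexity"]] - 1), 1e-2)
  # iid noise: Var(diff1) = 2 sigma^2, Var(diff2) = 6 sigma^2
  set.seed(3)
  hn <- hjorth(rnorm(1e4))
  expect_lt(abs(hn[["mobility"]] - sqrt(2)), 0.05)
  expect_lt(abs(hn[["complexity"]] - sqrt(3) / sqrt(2)), 0.05)
  # scale invariance
  set.seed(4)
  x <- rnorm(300)
  expect_equal(hjorth(5 * x), hjorth(x), tolerance = 1e-12)
  expect_error(hjorth(c(1, 2)), "too short")
})

test_that("extraction emits the named 65-column band-major grid", {
  rec <- simulate_recording(default_profiles()$FNSZ, 3, seed = 51)
  fm <- extract_features(rec)
  cols <- feature_columns(fm)
  expect_length(cols, 65)
  expect_equal(cols, feature_names())
  expect_equal(anyDuplicated(cols), 0)
  expect_equal(nrow(fm), 5)
  expect_true(all(is.finite(as.matrix(fm[cols]))))
  # names reshape losslessly to the 5 x 13 grid
  grid <- matrix(cols, nrow = 5, byrow = TRUE)
  expect_equal(dim(grid), c(5, 13))
  expect_true(all(startsWith(grid[5, ], "gamma_")))
  # single band -> 13 columns
  fm1 <- extract_features(rec, bands = eeg_bands()[1, ])
  expect_length(feature_columns(fm1), 13)
})

test_that("channel averaging is the identity for replicated channels", {
  rec <- simulate_recording(default_profiles()$TCSZ, 3, n_channels = 1,
                            seed = 52)
  rep3 <- eeg_recording(rec$signal[c(1, 1, 1), ], rec$fs, rec$label,
                        rec$recording_id)
  f1 <- extract_features(rec)
  f3 <- extract_features(rep3)
  expect_equal(as.matrix(f3[feature_columns(f3)]),
               as.matrix(f1[feature_columns(f1)]), tolerance = 1e-12)
})

test_that("standardization is fit on the requested rows only", {
  fm <- random_feature_tbl(n = 120, seed = 6)
  std <- standardize_features(fm)
  z <- as.matrix(std$features[feature_columns(fm)])
  expect_true(all(abs(colMeans(z)) < 1e-9))
  expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-9))
  # constant column -> zeros and a flag
  fm$theta_hurst <- 1
  std2 <- standardize_features(fm)
  expect_true("theta_hurst" %in% std2$constant)
  expect_true(all(std2$features$theta_hurst == 0))
  # held-out rows transformed with training statistics
  train <- 1:80
  std3 <- standardize_features(fm, fit_rows = train)
  held <- std3$features$gamma_variance[81:120]
  expect_gt(abs(mean(held)), 1e-6)
  expect_equal(std3$center[["gamma_variance"]],
               mean(fm$gamma_variance[train]))
  expect_equal(apply_standardizer(std3, fm[81:120, ])$gamma_variance, held)
  expect_error(standardize_features(fm, integer(0)), "nonempty")
})
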