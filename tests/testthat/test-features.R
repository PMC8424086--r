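test_that("PC1 recovers an axis-aligned signal exactly", {
  x <- sin(seq(0, 20, by = 0.01))
  a <- cbind(x, 0 * x, 0 * x)
  s <- pc1_scores(a)
  expect_equal(as.numeric(s), x - mean(x), tolerance = 1e-12)
  expect_equal(attr(s, "explained"), 1, tolerance = 1e-12)
})

test_that("PC1 score variance is invariant under rotation of the axes", {
  withr::local_seed(41)
  a <- matrix(rnorm(3000), ncol = 3) %*% diag(c(2, 1, 0.5))
  R <- rotation_matrix(c(1, 2, 3), 0.83)
  v1 <- var(as.numeric(pc1_scores(a)))
  v2 <- var(as.numeric(pc1_scores(a %*% t(R))))
  expect_equal(v1, v2, tolerance = 1e-9)
})

test_that("PC1 variance matches the eigendecomposition oracle", {
  withr::local_seed(42)
  a <- matrix(rnorm(3000), ncol = 3) %*% diag(c(2, 1, 0.5))  # cov diag(4,1,.25)
  s <- pc1_scores(a)
  # oracle: largest eigenvalue of the sample covariance, and prcomp
  ev <- eigen(stats::cov(a), symmetric = TRUE)$values[1]
  expect_equal(var(as.numeric(s)), ev, tolerance = 1e-9)
  pr <- stats::prcomp(a)
  expect_equal(var(as.numeric(s)), pr$sdev[1]^2, tolerance = 1e-9)
  expect_equal(ev, 4, tolerance = 0.4)  # sampling error at n = 1000
})

test_that("zero-variance signals are degenerate for PC1", {
  expect_error(pc1_scores(matrix(1, 100, 3)), class = "kc_degenerate_signal_error")
})

test_that("kurtosis matches closed forms and the moment oracle", {
  withr::local_seed(43)
  g <- rnorm(1e5)
  expect_equal(kurtosis_pearson(g), 3, tolerance = 0.1 / 3)
  expect_identical(kurtosis_pearson(rep(c(-1, 1), 4)), 1)
  x <- c(0, 0, 0, 0, 0, 0, 0, 10)
  expect_equal(kurtosis_pearson(x), kurtosis_moment_oracle(x), tolerance = 1e-12)
  # cross-check against e1071 (Pearson = excess type-1 + 3)
  skip_if_not_installed("e1071")
  y <- rgamma(5000, shape = 2)
  expect_equal(kurtosis_pearson(y), e1071::kurtosis(y, type = 1) + 3,
               tolerance = 1e-9)
})

test_that("kurtosis is >= 1 for arbitrary samples (Pearson bound)", {
  withr::local_seed(44)
  for (i in 1:50) {
    x <- switch(1 + i %% 4,
                rnorm(50), rexp(50), sample(c(-1, 1), 50, replace = TRUE),
                rcauchy(50))
    expect_gte(kurtosis_pearson(x), 1)
  }
})

test_that("jerk matches analytic derivatives", {
  fs <- 150
  t <- seq(0, 10, by = 1 / fs)
  const <- cbind(rep(2, length(t)), rep(-1, length(t)), rep(0.5, length(t)))
  expect_equal(max(jerk(const, fs)), 0)
  ramp <- cbind(3 * t, 0 * t, 0 * t)
  expect_equal(jerk(ramp, fs), rep(3, length(t) - 1), tolerance = 1e-9)
  f <- 2
  sine <- cbind(sin(2 * pi * f * t), 0 * t, 0 * t)
  j <- jerk(sine, fs)
  tm <- (t[-1] + t[-length(t)]) / 2  # first differences live at midpoints
  expect_lt(max(abs(j - abs(2 * pi * f * cos(2 * pi * f * tm)))),
            0.01 * 2 * pi * f)
})

test_that("pair_xcorr attains 1 at lag 0 for identical series", {
  withr::local_seed(45)
  j <- abs(rnorm(3000))
  r <- pair_xcorr(j, j, fs = 150)
  expect_equal(as.numeric(r), 1, tolerance = 1e-12)
  expect_identical(attr(r, "lag_s"), 0)
})

test_that("pair_xcorr recovers a pure shift at the shifted lag", {
  withr::local_seed(46)
  n <- 40000; k <- 10; fs <- 150  # k/n small so edge truncation stays < 1e-3
  x <- as.numeric(stats::filter(rnorm(n + k), rep(1 / 5, 5), sides = 2))
  x[is.na(x)] <- 0
  a <- x[1:n]
  b <- x[(1 + k):(n + k)]  # b leads a by k samples
  r <- pair_xcorr(a, b, fs = fs, max_lag_s = 2)
  expect_equal(as.numeric(r), 1, tolerance = 1e-3)
  expect_equal(abs(attr(r, "lag_s")), k / fs, tolerance = 1e-9)
})

test_that("pair_xcorr equals the ccf oracle at every lag", {
  withr::local_seed(47)
  n <- 2000; fs <- 100; L <- 50
  a <- rnorm(n); b <- rnorm(n)
  # oracle: stats::ccf uses the same coefficient normalization
  cc <- stats::ccf(a, b, lag.max = L, plot = FALSE, demean = TRUE)
  oracle_max <- max(cc$acf)
  r <- pair_xcorr(a, b, fs = fs, max_lag_s = L / fs)
  expect_equal(as.numeric(r), oracle_max, tolerance = 1e-9)
  expect_lt(as.numeric(r), 0.15)  # independent noise: small peak
})

test_that("pair_xcorr is symmetric and rejects degenerate input", {
  withr::local_seed(48)
  a <- abs(rnorm(1000)); b <- abs(rnorm(1000))
  expect_equal(as.numeric(pair_xcorr(a, b, fs = 100)),
               as.numeric(pair_xcorr(b, a, fs = 100)), tolerance = 1e-12)
  expect_error(pair_xcorr(a, rep(1, 1000), fs = 100),
               class = "kc_degenerate_signal_error")
})

test_that("identical limbs give unit cross-correlations and equal kurtosis", {
  rec <- make_uniform_recording(random_accel_fun(51), duration_s = 61)
  rec <- highpass(rec)
  f <- extract_features(rec)
  expect_equal(f$xcorr_upper, 1, tolerance = 1e-9)
  expect_equal(f$xcorr_lower, 1, tolerance = 1e-9)
  expect_equal(f$kur_LW, f$kur_RA, tolerance = 1e-9)
})

test_that("independent white-noise limbs look Gaussian and uncorrelated", {
  withr::local_seed(52)
  rec <- make_recording(function(l, t) matrix(rnorm(3 * length(t)), ncol = 3),
                        duration_s = 120, fs = 150)
  f <- suppressWarnings(extract_features(rec, max_lag_s = 2))
  for (k in c(f$kur_LW, f$kur_RW, f$kur_LA, f$kur_RA)) {
    expect_equal(k, 3, tolerance = 0.1)
  }
  expect_lt(f$xcorr_upper, 0.1)
  expect_lt(f$xcorr_lower, 0.1)
})

test_that("a dead sensor is reported by limb", {
  rec <- make_recording(function(l, t) {
    if (l == "LA") matrix(0, length(t), 3) else random_accel_fun(53)(t)
  }, duration_s = 30)
  err <- expect_error(suppressWarnings(extract_features(rec)),
                      class = "kc_degenerate_signal_error")
  expect_identical(err$where, "LA")
})

test_that("features are invariant to amplitude scale and limb rotation", {
  rec <- make_recording(function(l, t) random_accel_fun(match(l, c("LW", "RW", "LA", "RA")) * 7)(t),
                        duration_s = 61)
  rec <- highpass(rec)
  f0 <- extract_features(rec)
  f_scaled <- extract_features(scale_recording(rec, 3.7))
  for (col in c("kur_LW", "kur_RW", "kur_LA", "kur_RA", "xcorr_upper", "xcorr_lower")) {
    expect_equal(f_scaled[[col]], f0[[col]], tolerance = 1e-9)
  }
  R <- rotation_matrix(c(0.2, -1, 0.5), 1.1)
  f_rot <- extract_features(rotate_limb(rec, "RW", R))
  expect_equal(f_rot$kur_RW, f0$kur_RW, tolerance = 1e-9)
  expect_equal(f_rot$xcorr_upper, f0$xcorr_upper, tolerance = 1e-9)
})
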