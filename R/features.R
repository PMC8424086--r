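#' First principal component of a tri-axial acceleration signal
#'
#' Projects the centered 3-axis signal onto the eigenvector of the largest
#' eigenvalue of the 3x3 sample covariance, collapsing each limb's movement
#' onto its dominant spatial direction. The score series is invariant (up to
#' sign) under any fixed rotation of the sensor axes, so it does not depend
#' on how the device was strapped on. Sign convention: the first nonzero
#' loading of the eigenvector is positive.
#'
#' @param accel A numeric matrix or data frame with 3 columns (ax, ay, az),
#'   one row per sample.
#' @return Numeric vector of PC1 scores, with the fraction of total variance
#'   explained in attribute `"explained"`.
#' @export
pc1_scores <- function(accel) {
  a <- as.matrix(accel)
  stopifnot(ncol(a) == 3)
  if (nrow(a) < 4) degenerate_signal_error("pc1_scores (<4 samples)")
  a <- sweep(a, 2, colMeans(a))
  cv <- crossprod(a) / (nrow(a) - 1)
  if (sum(diag(cv)) <= 0) degenerate_signal_error("pc1_scores (zero variance)")
  e <- eigen(cv, symmetric = TRUE)
  v <- e$vectors[, 1]
  nz <- which(abs(v) > .Machine$double.eps^0.5)[1]
  if (!is.na(nz) && v[nz] < 0) v <- -v
  scores <- drop(a %*% v)
  attr(scores, "explained") <- e$values[1] / sum(e$values)
  scores
}

#' Pearson kurtosis of a series
#'
#' The non-excess, biased-moment kurtosis m4/m2^2, where mk is the k-th
#' central sample moment (divisor n). It measures the peakedness/tailedness
#' of the amplitude distribution: 3 for a Gaussian, >= 1 for any
#' distribution, with the lower bound attained by a symmetric two-point
#' distribution. Sparse, stereotyped movement (long quiet stretches broken
#' by similar bursts) produces heavy-tailed score distributions and hence
#' high kurtosis; varied, frequent movement yields values nearer the
#' Gaussian 3.
#'
#' @param x Numeric vector, at least 4 samples with positive variance.
#' @return The kurtosis (dimensionless, >= 1).
#' @export
kurtosis_pearson <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 4) degenerate_signal_error("kurtosis (<4 samples)")
  x <- x - mean(x)
  m2 <- mean(x^2)
  if (m2 <= 0) degenerate_signal_error("kurtosis (zero variance)")
  mean(x^4) / m2^2
}

#' Jerk magnitude of a limb's acceleration
#'
#' Jerk is the time derivative of acceleration. Each axis is differentiated
#' by first difference over the sampling interval and the three derivative
#' components are combined by Euclidean norm, giving an orientation-invariant
#' movement-intensity series of length n - 1.
#'
#' @param accel Matrix/data frame with columns ax, ay, az on a uniform grid.
#' @param fs Sampling rate of the grid (Hz).
#' @return Numeric vector of jerk magnitudes (m/s^3), length `nrow(accel) - 1`.
#' @export
jerk <- function(accel, fs) {
  a <- as.matrix(accel)
  stopifnot(ncol(a) == 3, fs > 0)
  if (nrow(a) < 2) degenerate_signal_error("jerk (<2 samples)")
  d <- diff(a) * fs
  sqrt(rowSums(d^2))
}

#' Peak normalized cross-correlation between two jerk series
#'
#' Both series are mean-centered and the coefficient-normalized
#' cross-correlation (division by the product of the centered series norms,
#' so the lag-0 value equals the Pearson correlation) is evaluated at every
#' integer lag with |lag| <= `max_lag_s * fs`; the maximum over lags is
#' returned. The lag window tolerates the small latencies with which
#' near-simultaneous limb movements co-occur, while a bounded window avoids
#' spurious far-lag maxima.
#'
#' @param jerk_a,jerk_b Equal-length numeric series with positive variance.
#' @param fs Sampling rate (Hz).
#' @param max_lag_s Half-width of the lag window in seconds (default 2).
#' @return The peak correlation (in `[-1, 1]`), with the lag (s) at which it
#'   is attained in attribute `"lag_s"`.
#' @export
pair_xcorr <- function(jerk_a, jerk_b, fs, max_lag_s = 2) {
  a <- as.numeric(jerk_a); b <- as.numeric(jerk_b)
  stopifnot(length(a) == length(b), fs > 0, max_lag_s >= 0)
  n <- length(a)
  if (n < 2) degenerate_signal_error("pair_xcorr (<2 samples)")
  a <- a - mean(a); b <- b - mean(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) degenerate_signal_error("pair_xcorr (zero variance)")
  lmax <- min(as.integer(round(max_lag_s * fs)), n - 1L)
  lags <- (-lmax):lmax
  r <- vapply(lags, function(k) {
    if (k >= 0) sum(a[1:(n - k)] * b[(1 + k):n]) else sum(a[(1 - k):n] * b[1:(n + k)])
  }, numeric(1)) / (na * nb)
  i <- which.max(r)
  out <- r[i]
  attr(out, "lag_s") <- lags[i] / fs
  out
}

#' Extract the six per-subject movement features
#'
#' For each limb, the Pearson kurtosis of the first principal component of
#' its (gravity-removed) acceleration; for the upper (LW-RW) and lower
#' (LA-RA) limb pairs, the peak normalized cross-correlation of the jerk
#' magnitudes. Kurtosis captures how stereotyped/sparse each limb's movement
#' is; jerk cross-correlation captures how synchronously the paired limbs
#' move.
#'
#' @param rec A synchronized, high-pass filtered `kc_recording`.
#' @param max_lag_s Lag window for [pair_xcorr()] (seconds, default 2).
#' @return A one-row tibble: `subject_id`, `kur_LW`, `kur_RW`, `kur_LA`,
#'   `kur_RA`, `xcorr_upper`, `xcorr_lower`, `gm_label`.
#' @export
extract_features <- function(rec, max_lag_s = 2) {
  stopifnot(inherits(rec, "kc_recording"))
  if (!is_synchronized(rec)) not_synchronized_error("extract_features()")
  if (!isTRUE(attr(rec, "highpassed"))) {
    warn("extract_features() assumes gravity was removed; run highpass() first")
  }
  fs <- attr(rec, "nominal_rate_hz")
  kur <- vapply(LIMB_IDS, function(l) {
    d <- limb_samples(rec, l)[, c("ax", "ay", "az")]
    relabel_degenerate(
      tryCatch(kurtosis_pearson(pc1_scores(d)), error = function(e) e), l)
  }, numeric(1))
  jerks <- lapply(LIMB_IDS, function(l) {
    jerk(limb_samples(rec, l)[, c("ax", "ay", "az")], fs)
  })
  names(jerks) <- LIMB_IDS
  xco <- function(pair, a, b) {
    relabel_degenerate(
      tryCatch(as.numeric(pair_xcorr(jerks[[a]], jerks[[b]], fs, max_lag_s)),
               error = function(e) e),
      pair)
  }
  tibble(subject_id = subject_id(rec),
         kur_LW = kur[["LW"]], kur_RW = kur[["RW"]],
         kur_LA = kur[["LA"]], kur_RA = kur[["RA"]],
         xcorr_upper = xco("upper", "LW", "RW"),
         xcorr_lower = xco("lower", "LA", "RA"),
         gm_label = gm_label(rec))
}

# Rethrow a degenerate-signal condition naming the limb or pair it came from.
relabel_degenerate <- function(x, where) {
  if (inherits(x, "kc_degenerate_signal_error")) degenerate_signal_error(where)
  if (inherits(x, "error")) stop(x)
  x
}
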