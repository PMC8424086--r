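# Fixture builders: recordings constructed in code, no stored data.

# Uniform-grid recording where every limb carries the signal returned by
# `limb_fun(limb, t)` (an n x 3 matrix or a list(ax, ay, az)).
make_recording <- function(limb_fun, duration_s = 60, fs = 150,
                           subject_id = "s1", gm_label = NA_character_,
                           synchronized = TRUE, t0 = 0) {
  t <- t0 + seq(0, duration_s, by = 1 / fs)
  data <- dplyr::bind_rows(lapply(c("LW", "RW", "LA", "RA"), function(l) {
    a <- limb_fun(l, t)
    a <- as.matrix(as.data.frame(a))
    tibble::tibble(limb = l, t_s = t, ax = a[, 1], ay = a[, 2], az = a[, 3])
  }))
  new_recording(data, subject_id = subject_id, nominal_rate_hz = fs,
                gm_label = gm_label, synchronized = synchronized)
}

# All four limbs share one tri-axial signal.
make_uniform_recording <- function(accel_fun, ...) {
  make_recording(function(l, t) accel_fun(t), ...)
}

# Smooth random test signal with movement-band content (sum of sinusoids).
bandlimited_signal <- function(t, seed = 1, n_components = 5,
                               fmin = 0.3, fmax = 5, amp = 1) {
  withr::with_seed(seed, {
    f <- runif(n_components, fmin, fmax)
    ph <- runif(n_components, 0, 2 * pi)
    a <- runif(n_components, 0.3, 1) * amp
  })
  rowSums(sapply(seq_along(f), function(i) a[i] * sin(2 * pi * f[i] * t + ph[i])))
}

random_accel_fun <- function(seed) {
  function(t) cbind(bandlimited_signal(t, seed),
                    bandlimited_signal(t, seed + 1000),
                    bandlimited_signal(t, seed + 2000))
}

# Rotation matrix about an arbitrary axis (Rodrigues).
rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

rotate_limb <- function(rec, limb, R) {
  idx <- rec$limb == limb
  a <- as.matrix(rec[idx, c("ax", "ay", "az")]) %*% t(R)
  rec$ax[idx] <- a[, 1]; rec$ay[idx] <- a[, 2]; rec$az[idx] <- a[, 3]
  rec
}

scale_recording <- function(rec, c) {
  rec$ax <- rec$ax * c; rec$ay <- rec$ay * c; rec$az <- rec$az * c
  rec
}

# A small synthetic cohort for end-to-end invariance checks.
invariance_cohort <- function(duration_s = 60, seed = 11) {
  labels <- c("N", "N", "PR", "PR", "CS", "CS")
  lapply(seq_along(labels), function(i) {
    simulate_subject(group_params(labels[i]),
                     subject_id = sprintf("inv%02d", i),
                     duration_s = duration_s, seed = seed + i)
  })
}

# Independent brute-force oracles -------------------------------------------

# AUC as the fraction of concordant positive/negative pairs, ties 1/2.
auc_pairwise_oracle <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  conc <- 0
  for (i in seq_along(sp)) {
    for (j in seq_along(sn)) {
      conc <- conc + (sp[i] > sn[j]) + 0.5 * (sp[i] == sn[j])
    }
  }
  conc / (length(sp) * length(sn))
}

# Youden cutoff by exhaustive scan over midpoint thresholds.
youden_scan_oracle <- function(scores, pos) {
  v <- sort(unique(scores))
  thr <- if (length(v) > 1) (v[-1] + v[-length(v)]) / 2 else v
  best <- NULL
  for (t in thr) {
    sens <- mean(scores[pos] > t)
    spec <- mean(scores[!pos] <= t)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && (spec > best$spec ||
          (spec == best$spec && t < best$cutoff)))) {
      best <- list(cutoff = t, sens = sens, spec = spec, j = j)
    }
  }
  best
}

# k-th central moment ratio m4/m2^2 computed longhand.
kurtosis_moment_oracle <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m4 <- sum((x - mu)^4) / n
  m4 / m2^2
}
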