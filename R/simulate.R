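#' Group parameter sets for the movement simulator
#'
#' Each clinical general-movement class is encoded as a regime of a
#' burst-process generator. Limb movement is a superposition of short
#' oscillatory bursts: a Poisson stream shared by all four limbs (fraction
#' `coupling` of the per-limb rate, copied to every limb with per-limb
#' timing jitter — whole-body synchrony) plus an independent per-limb
#' stream. Burst peak amplitude, duration and oscillation frequency are
#' drawn per burst from gamma distributions with the given means and
#' coefficients of variation; low CVs yield stereotyped, self-similar
#' movements.
#'
#' Default regimes (simulator conventions encoding the clinical class
#' descriptions, not measured values):
#' * `N` (normal): frequent, varied, essentially independent limb movement —
#'   `burst_rate_hz` 0.25, `amp_cv` 0.6, `dur_cv` 0.6, `coupling` 0.1.
#' * `PR` (poor repertoire): sparse, stereotyped, independent — rate 0.08,
#'   `amp_cv` 0.15, `dur_cv` 0.15, `coupling` 0.1.
#' * `CS` (cramped synchronized): sparse, stereotyped, and co-occurring
#'   across limbs — rate 0.08, `amp_cv` 0.15, `coupling` 0.9,
#'   `jitter_s` 0.05.
#'
#' @param label `"N"`, `"PR"`, or `"CS"`.
#' @param ... Named overrides of any parameter field.
#' @return A list of class `kc_group_params`.
#' @export
group_params <- function(label = c("N", "PR", "CS"), ...) {
  label <- match.arg(label)
  base <- list(
    label = label,
    burst_rate_hz = 0.25,   # mean bursts per second per limb
    amp_mean = 4,           # burst peak acceleration, m/s^2
    amp_cv = 0.6,
    dur_mean_s = 1.2,       # burst duration
    dur_cv = 0.6,
    freq_mean_hz = 2.5,     # intra-burst oscillation frequency
    freq_cv = 0.3,
    coupling = 0.1,         # fraction of bursts shared by all four limbs
    jitter_s = 0.1,         # timing jitter of shared bursts across limbs
    noise_rms = 0.02,       # white sensor noise per axis, m/s^2
    gravity_amp = GRAVITY_MS2,
    gravity_wander = 0.02,  # relative magnitude of postural re-orientation
    gravity_timescale_s = 60
  )
  presets <- list(
    N  = list(),
    PR = list(burst_rate_hz = 0.08, amp_cv = 0.15, dur_mean_s = 0.6,
              dur_cv = 0.15, freq_cv = 0.1),
    CS = list(burst_rate_hz = 0.08, amp_cv = 0.15, dur_mean_s = 0.6,
              dur_cv = 0.15, freq_cv = 0.1, coupling = 0.9, jitter_s = 0.05)
  )
  p <- utils::modifyList(base, presets[[label]])
  over <- list(...)
  if (length(over) > 0) {
    bad <- setdiff(names(over), names(p))
    if (length(bad) > 0) {
      format_error(sprintf("unknown group parameter(s): %s", paste(bad, collapse = ", ")))
    }
    p <- utils::modifyList(p, over)
  }
  stopifnot(p$burst_rate_hz >= 0, p$amp_mean > 0, p$dur_mean_s > 0,
            p$freq_mean_hz > 0, p$coupling >= 0, p$coupling <= 1,
            p$jitter_s >= 0, p$noise_rms >= 0)
  class(p) <- c("kc_group_params", "list")
  p
}

# gamma draw with given mean and coefficient of variation (cv = 0 -> constant)
rgamma_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  shape <- 1 / cv^2
  rgamma(n, shape = shape, scale = mean / shape)
}

# Draw a burst table: onset, peak amplitude, duration, frequency, phase.
draw_bursts <- function(rate_hz, duration_s, p) {
  n <- rpois(1, rate_hz * duration_s)
  tibble(
    onset = sort(runif(n, 0, duration_s)),
    amp = rgamma_cv(n, p$amp_mean, p$amp_cv),
    dur = pmax(rgamma_cv(n, p$dur_mean_s, p$dur_cv), 0.15),
    freq = pmin(pmax(rgamma_cv(n, p$freq_mean_hz, p$freq_cv), 0.3), 8),
    phase = runif(n, 0, 2 * pi)
  )
}

# Random unit vector in 3-D.
runif_sphere <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# Evaluate a burst table on a uniform time grid, each burst along its own
# random spatial direction: amp * hann((t-t0)/dur) * sin(2*pi*f*(t-t0)+phi).
eval_bursts <- function(bursts, t, directions) {
  n <- length(t)
  acc <- matrix(0, n, 3)
  if (nrow(bursts) == 0) return(acc)
  dt <- t[2] - t[1]
  for (i in seq_len(nrow(bursts))) {
    t0 <- bursts$onset[i]; D <- bursts$dur[i]
    i0 <- max(1L, floor((t0 - t[1]) / dt) + 1L)
    i1 <- min(n, ceiling((t0 + D - t[1]) / dt) + 1L)
    if (i1 < i0) next
    tt <- t[i0:i1] - t0
    inside <- tt >= 0 & tt <= D
    w <- numeric(length(tt))
    w[inside] <- 0.5 * (1 - cos(2 * pi * tt[inside] / D)) *
      sin(2 * pi * bursts$freq[i] * tt[inside] + bursts$phase[i])
    acc[i0:i1, ] <- acc[i0:i1, ] + bursts$amp[i] * outer(w, directions[i, ])
  }
  acc
}

# Slowly re-orienting gravity vector: an Ornstein-Uhlenbeck perturbation of
# an initial orientation on 1 s knots, spline-interpolated to sample times
# and rescaled to gravity_amp.
gravity_track <- function(p, duration_s, t_eval) {
  knots <- seq(0, duration_s + 2, by = 1)
  nk <- length(knots)
  g0 <- runif_sphere()
  theta <- 1 / p$gravity_timescale_s
  sig <- p$gravity_wander * sqrt(2 * theta)
  dev <- matrix(0, nk, 3)
  for (k in 2:nk) {
    dev[k, ] <- dev[k - 1, ] * (1 - theta) + sig * rnorm(3)
  }
  raw <- sweep(dev, 2, g0, `+`)
  raw <- raw / sqrt(rowSums(raw^2))
  vapply(1:3, function(j) {
    stats::spline(knots, raw[, j], xout = t_eval)$y * p$gravity_amp
  }, numeric(length(t_eval)))
}

#' Simulate one subject's four-limb recording
#'
#' Generates the device-local, pre-synchronization streams: burst onsets
#' from the shared (rate `coupling * burst_rate_hz`, copied to all limbs
#' with per-limb timing jitter) and independent (rate
#' `(1 - coupling) * burst_rate_hz`) Poisson streams; each burst a
#' Hann-windowed sinusoid along a random per-limb direction; a slowly
#' re-orienting gravity vector; white sensor noise; and a per-device clock
#' offset (uniform in `[0, clock_jitter_ms]`) with a slightly perturbed
#' actual sampling rate, both reflected in the recorded timestamps.
#'
#' @param params A `kc_group_params` regime, see [group_params()].
#' @param subject_id Subject identifier.
#' @param duration_s Recording length in seconds (default 600, the standard
#'   10-minute session).
#' @param rate_hz Nominal device sampling rate (default 150).
#' @param clock_jitter_ms Maximum per-device clock offset, ms (default 0.5).
#' @param seed Optional seed; when given, the draw is reproducible and the
#'   caller's RNG state is left untouched.
#' @return An unsynchronized `kc_recording` with `gm_label` set.
#' @export
simulate_subject <- function(params, subject_id = "sim01", duration_s = 600,
                             rate_hz = 150, clock_jitter_ms = 0.5, seed = NULL) {
  stopifnot(inherits(params, "kc_group_params"), duration_s > 0, rate_hz > 0)
  run <- function() {
    p <- params
    shared <- draw_bursts(p$coupling * p$burst_rate_hz, duration_s, p)
    own <- lapply(LIMB_IDS, function(l) {
      draw_bursts((1 - p$coupling) * p$burst_rate_hz, duration_s, p)
    })
    names(own) <- LIMB_IDS
    # per-limb realization of the shared stream: same amp/dur/freq/phase,
    # jittered onset, own spatial direction
    shared_limb <- lapply(LIMB_IDS, function(l) {
      b <- shared
      if (nrow(b) > 0 && p$jitter_s > 0) {
        b$onset <- b$onset + rnorm(nrow(b), 0, p$jitter_s)
      }
      b
    })
    names(shared_limb) <- LIMB_IDS
    offs <- runif(4, 0, clock_jitter_ms / 1000)
    rates <- rate_hz * (1 + runif(4, -2e-5, 2e-5))
    data <- vector("list", 4)
    for (k in seq_along(LIMB_IDS)) {
      l <- LIMB_IDS[k]
      nsamp <- floor((duration_s - offs[k]) * rates[k]) + 1L
      t <- offs[k] + (seq_len(nsamp) - 1L) / rates[k]
      bursts <- dplyr::bind_rows(shared_limb[[l]], own[[l]])
      dirs <- if (nrow(bursts) > 0) {
        t(vapply(seq_len(nrow(bursts)), function(i) runif_sphere(), numeric(3)))
      } else {
        matrix(0, 0, 3)
      }
      acc <- eval_bursts(bursts, t, dirs)
      acc <- acc + gravity_track(p, duration_s, t)
      if (p$noise_rms > 0) {
        acc <- acc + matrix(rnorm(3 * nsamp, 0, p$noise_rms), nsamp, 3)
      }
      data[[k]] <- tibble(limb = l, t_s = t,
                          ax = acc[, 1], ay = acc[, 2], az = acc[, 3])
    }
    new_recording(dplyr::bind_rows(data), subject_id = subject_id,
                  nominal_rate_hz = rate_hz, gm_label = params$label,
                  synchronized = FALSE)
  }
  if (is.null(seed)) run() else with_preserved_seed({ set.seed(seed); run() })
}

#' Simulate a labelled cohort of subjects
#'
#' Subjects are drawn independently; each subject gets its own RNG
#' substream derived once from the cohort seed, so the draw for subject *k*
#' does not depend on how many samples earlier subjects consumed.
#'
#' @param n_per_group Named counts, e.g. `c(N = 43, PR = 17, CS = 8)` (the
#'   default, matching a typical at-risk cohort composition with roughly
#'   one-third abnormal movers).
#' @param duration_s,rate_hz,clock_jitter_ms Passed to [simulate_subject()].
#' @param seed Cohort seed (default 127).
#' @param group_params Optional named list of `kc_group_params` overriding
#'   the [group_params()] defaults per label.
#' @return List of `kc_recording` objects, one per subject.
#' @export
simulate_cohort <- function(n_per_group = c(N = 43, PR = 17, CS = 8),
                            duration_s = 600, rate_hz = 150,
                            clock_jitter_ms = 0.5, seed = 127,
                            group_params = NULL) {
  labels <- rep(names(n_per_group), times = n_per_group)
  if (length(labels) < 2) {
    degenerate_cohort_error(message = "a cohort needs at least 2 subjects")
  }
  stopifnot(all(labels %in% GM_LABELS))
  pars <- lapply(stats::setNames(nm = GM_LABELS), function(l) {
    gp <- group_params[[l]]
    if (is.null(gp)) kcindex::group_params(l) else gp
  })
  seeds <- with_preserved_seed({
    set.seed(seed)
    sample.int(2147483646L, length(labels))
  })
  ids <- unlist(lapply(unique(labels), function(l) {
    sprintf("%s%02d", l, seq_len(sum(labels == l)))
  }))
  purrr::map2(labels, seq_along(labels), function(l, i) {
    simulate_subject(pars[[l]], subject_id = ids[i], duration_s = duration_s,
                     rate_hz = rate_hz, clock_jitter_ms = clock_jitter_ms,
                     seed = seeds[i])
  })
}

#' Write a simulated cohort to disk in the standard CSV + JSON layout
#'
#' @param recs List of `kc_recording` objects.
#' @param dir Output directory; one subdirectory per subject.
#' @return Invisibly, the subject directories.
#' @export
write_cohort <- function(recs, dir) {
  paths <- vapply(recs, function(r) {
    d <- file.path(dir, subject_id(r))
    write_subject(r, d)
    d
  }, character(1))
  invisible(paths)
}
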