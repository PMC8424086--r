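#' Remove the gravitational component with a zero-phase high-pass filter
#'
#' Gravity appears in each axis as a large, slowly re-orienting offset
#' (≈9.81 m/s^2 projected on the sensor axes as posture changes), while
#' infant limb movement lives well above ~0.1 Hz. A 4th-order Butterworth
#' high-pass with a 0.05 Hz cutoff, applied with zero phase, removes the
#' gravitational/postural component without shifting movement timing —
#' important because inter-limb jerk cross-correlation downstream is a
#' timing measure.
#'
#' The filter is realized in the frequency domain: each axis is
#' odd-reflection padded by three filter time constants (3/`cutoff_hz`
#' seconds, suppressing edge transients), and its spectrum multiplied by
#' the Butterworth squared-magnitude response — the response a
#' forward-backward time-domain pass realizes, but exactly linear, exactly
#' phase-free, and with an exact zero at DC even at very low normalized
#' cutoffs. `zero_phase = FALSE` applies the complex (causal, single-pass)
#' response instead.
#'
#' @param rec A synchronized `kc_recording`.
#' @param cutoff_hz High-pass cutoff frequency (Hz). Default 0.05.
#' @param order Butterworth order. Default 4.
#' @param zero_phase Apply forward-backward (no phase lag). Default `TRUE`;
#'   `FALSE` gives a single causal pass.
#' @return The filtered `kc_recording`; each axis has (numerically) zero mean.
#' @export
highpass <- function(rec, cutoff_hz = 0.05, order = 4, zero_phase = TRUE) {
  stopifnot(inherits(rec, "kc_recording"))
  if (!is_synchronized(rec)) not_synchronized_error("highpass()")
  fs <- attr(rec, "nominal_rate_hz")
  if (!(cutoff_hz > 0 && cutoff_hz < fs / 2)) {
    format_error(sprintf("cutoff %g Hz outside (0, Nyquist = %g Hz)", cutoff_hz, fs / 2))
  }
  stopifnot(order >= 1)
  dur <- recording_duration(rec)
  if (dur < 3 / cutoff_hz) {
    warn(sprintf(
      "recording (%.1f s) is shorter than 3/cutoff (%.0f s); high-pass response near the cutoff will be poorly realized",
      dur, 3 / cutoff_hz))
  }
  data <- rec |>
    dplyr::group_by(.data$limb) |>
    dplyr::mutate(dplyr::across(
      c("ax", "ay", "az"),
      ~ butter_highpass_fd(.x, fs = fs, cutoff_hz = cutoff_hz, order = order,
                           npad = round(3 / cutoff_hz * fs),
                           zero_phase = zero_phase)
    )) |>
    dplyr::ungroup()
  out <- rebuild_recording(data, rec)
  attr(out, "highpassed") <- TRUE
  out
}

# Butterworth high-pass applied in the frequency domain on an odd-reflection
# padded copy of the series. Zero-phase mode multiplies the spectrum by the
# squared magnitude response (what a forward-backward time-domain pass
# realizes); causal mode by the complex response. The DC bin is exactly
# zero, and the operation is exactly linear — a time-domain ba recursion at
# a normalized cutoff of ~7e-4 amplifies roundoff to ~1e-7 relative, which
# would leak into the downstream scale/rotation invariances.
butter_highpass_fd <- function(x, fs, cutoff_hz, order, npad,
                               zero_phase = TRUE) {
  n <- length(x)
  # a constant axis has an exactly-zero high-pass image
  if (all(x == x[1])) return(numeric(n))
  npad <- min(npad, n - 1L)
  xp <- if (npad > 0) {
    c(2 * x[1] - x[(npad + 1L):2],
      x,
      2 * x[n] - x[(n - 1L):(n - npad)])
  } else {
    x
  }
  m <- stats::nextn(length(xp), c(2, 3, 5))
  xp <- c(xp, numeric(m - length(xp)))
  k <- 0:(m - 1)
  f <- ifelse(k <= m / 2, k, k - m) * fs / m
  if (zero_phase) {
    w <- (abs(f) / cutoff_hz)^(2 * order)
    H <- w / (1 + w)
  } else {
    # analog Butterworth high-pass response from the low-pass prototype poles
    pk <- exp(1i * pi * (2 * seq_len(order) + order - 1) / (2 * order))
    s <- 1i * f / cutoff_hz
    H <- s^order
    for (p in pk) H <- H / (s - p)
    H[f == 0] <- 0
  }
  y <- Re(stats::fft(stats::fft(xp) * H, inverse = TRUE)) / m
  y[(npad + 1L):(npad + n)]
}
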