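#' Synchronize the four limb streams onto one uniform time grid
#'
#' The four devices have independent timers: start offsets and actual
#' sampling rates differ slightly (sub-millisecond per sample), so raw
#' streams are not sample-aligned. This resamples every limb by linear
#' interpolation onto one uniform grid at `target_rate_hz`, covering the
#' intersection of the four device time spans (left-aligned to the latest
#' start, so no extrapolation occurs). With clock discrepancies below 1 ms
#' at a 150 Hz sample period of ~6.7 ms, linear interpolation error is
#' negligible; interpolation at existing knots is exact, so the operation is
#' idempotent on an already-uniform recording.
#'
#' @param rec A `kc_recording`.
#' @param target_rate_hz Grid rate; defaults to the recording's nominal rate.
#' @param min_duration_s Minimum usable overlap in seconds (checked with a
#'   5% tolerance); shorter overlaps raise an error. Default 600 s, the
#'   standard 10-minute observation.
#'
#' @return A synchronized `kc_recording`: all four limbs share one grid and
#'   sample count.
#' @export
synchronize <- function(rec, target_rate_hz = NULL, min_duration_s = 600) {
  stopifnot(inherits(rec, "kc_recording"))
  target_rate_hz <- target_rate_hz %||% attr(rec, "nominal_rate_hz")
  limbs <- lapply(LIMB_IDS, function(l) limb_samples(rec, l))
  names(limbs) <- LIMB_IDS
  for (l in LIMB_IDS) {
    if (nrow(limbs[[l]]) < 2) {
      degenerate_signal_error(sprintf("limb %s (<2 samples)", l))
    }
  }
  t0 <- max(vapply(limbs, function(d) d$t_s[1], numeric(1)))
  t1 <- min(vapply(limbs, function(d) d$t_s[nrow(d)], numeric(1)))
  overlap <- t1 - t0
  if (overlap < 0.95 * min_duration_s) {
    insufficient_overlap_error(overlap, min_duration_s)
  }
  n <- floor(overlap * target_rate_hz) + 1L
  grid <- t0 + (seq_len(n) - 1L) / target_rate_hz
  data <- dplyr::bind_rows(lapply(LIMB_IDS, function(l) {
    d <- limbs[[l]]
    tibble(limb = l, t_s = grid,
           ax = approx(d$t_s, d$ax, xout = grid)$y,
           ay = approx(d$t_s, d$ay, xout = grid)$y,
           az = approx(d$t_s, d$az, xout = grid)$y)
  }))
  out <- rebuild_recording(data, rec, synchronized = TRUE)
  attr(out, "nominal_rate_hz") <- target_rate_hz
  out
}

#' Drop an initial settling window
#'
#' Recording sessions conventionally start ~30 s after the sensors are
#' strapped on, so the infant settles before acquisition; when that delay
#' was not applied at acquisition time this trims it retrospectively. The
#' first `settle_s` seconds are removed from all four limbs identically.
#'
#' @param rec A synchronized `kc_recording`.
#' @param settle_s Seconds to discard from the start (default 0).
#' @return The trimmed `kc_recording`.
#' @export
trim_settling <- function(rec, settle_s = 0) {
  stopifnot(inherits(rec, "kc_recording"), settle_s >= 0)
  if (!is_synchronized(rec)) not_synchronized_error("trim_settling()")
  if (settle_s == 0) return(rec)
  t0 <- min(rec$t_s)
  dur <- max(rec$t_s) - t0
  if (settle_s >= dur) {
    empty_recording_error(sprintf(
      "settle_s = %g s is not shorter than the recording (%.1f s)", settle_s, dur))
  }
  keep <- rec$t_s >= t0 + settle_s
  rebuild_recording(rec[keep, ], rec)
}
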