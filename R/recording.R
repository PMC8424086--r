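#' Four-limb accelerometer recordings
#'
#' A `kc_recording` is a tibble in long format with one row per sample and
#' columns `limb` (`"LW"`, `"RW"`, `"LA"`, `"RA"` for left/right wrist and
#' left/right ankle), `t_s` (device timestamp in seconds since the shared
#' start of acquisition) and `ax`, `ay`, `az` (tri-axial acceleration in
#' m/s^2). Subject-level metadata travels in attributes: `subject_id`,
#' `gm_label` (clinical general-movement class `"N"`, `"PR"`, `"CS"`, or
#' `NA`), `nominal_rate_hz`, `pma_weeks`, and `synchronized` (whether all
#' four limbs share one uniform time grid).
#'
#' @param data A data frame with columns `limb`, `t_s`, `ax`, `ay`, `az`
#'   covering all four limbs.
#' @param subject_id Subject identifier string.
#' @param nominal_rate_hz Nominal sampling rate of the devices (Hz).
#' @param gm_label Optional clinical label (`"N"`, `"PR"`, or `"CS"`).
#' @param pma_weeks Optional post-menstrual age in weeks.
#' @param synchronized Whether the limbs already share a uniform common grid.
#'
#' @return A `kc_recording` tibble.
#' @export
new_recording <- function(data, subject_id, nominal_rate_hz = 150,
                          gm_label = NA_character_, pma_weeks = NA_real_,
                          synchronized = FALSE) {
  stopifnot(is.data.frame(data))
  needed <- c("limb", "t_s", "ax", "ay", "az")
  miss <- setdiff(needed, names(data))
  if (length(miss) > 0) {
    format_error(sprintf("recording table lacks column(s): %s",
                         paste(miss, collapse = ", ")))
  }
  if (!is.na(gm_label) && !gm_label %in% GM_LABELS) {
    format_error(sprintf("unknown gm_label '%s' (expected N, PR, or CS)", gm_label))
  }
  out <- as_tibble(data[needed])
  for (l in LIMB_IDS) {
    if (!l %in% out$limb) missing_limb_error(l)
  }
  attr(out, "subject_id") <- as.character(subject_id)
  attr(out, "gm_label") <- gm_label
  attr(out, "nominal_rate_hz") <- nominal_rate_hz
  attr(out, "pma_weeks") <- pma_weeks
  attr(out, "synchronized") <- isTRUE(synchronized)
  class(out) <- c("kc_recording", class(out))
  validate_recording(out)
  out
}

# Re-attach recording metadata after a transformation of the sample table.
rebuild_recording <- function(data, template, synchronized = NULL) {
  new_recording(data,
                subject_id = subject_id(template),
                nominal_rate_hz = attr(template, "nominal_rate_hz"),
                gm_label = gm_label(template),
                pma_weeks = attr(template, "pma_weeks"),
                synchronized = synchronized %||% is_synchronized(template))
}

validate_recording <- function(rec) {
  for (l in LIMB_IDS) {
    t <- limb_samples(rec, l)$t_s
    if (length(t) >= 2) {
      d <- diff(t)
      if (any(d <= 0)) {
        k <- which(d <= 0)[1] + 1L
        format_error(sprintf(
          "timestamps for limb %s are not strictly increasing at row %d (t = %g s)",
          l, k, t[k]), limb = l, row = k)
      }
      md <- median(d)
      nominal <- 1 / attr(rec, "nominal_rate_hz")
      if (abs(md - nominal) > 0.05 * nominal) {
        format_error(sprintf(
          "limb %s: median sampling interval %.6f s deviates >5%% from nominal %.6f s",
          l, md, nominal), limb = l)
      }
    }
  }
  invisible(rec)
}

#' @rdname new_recording
#' @param rec,x A `kc_recording`.
#' @export
subject_id <- function(rec) attr(rec, "subject_id")

#' @rdname new_recording
#' @export
gm_label <- function(rec) attr(rec, "gm_label")

#' @rdname new_recording
#' @export
is_synchronized <- function(rec) isTRUE(attr(rec, "synchronized"))

#' @rdname new_recording
#' @param limb One of `"LW"`, `"RW"`, `"LA"`, `"RA"`.
#' @export
limb_samples <- function(rec, limb) {
  rec[rec$limb == limb, c("t_s", "ax", "ay", "az"), drop = FALSE]
}

# Duration of the limb-span intersection, seconds.
recording_duration <- function(rec) {
  spans <- vapply(LIMB_IDS, function(l) {
    t <- limb_samples(rec, l)$t_s
    c(t[1], t[length(t)])
  }, numeric(2))
  max(0, min(spans[2, ]) - max(spans[1, ]))
}

#' @export
print.kc_recording <- function(x, ...) {
  n <- vapply(LIMB_IDS, function(l) nrow(limb_samples(x, l)), integer(1))
  cat(sprintf(
    "<kc_recording> subject %s | gm_label %s | %g Hz nominal | %s\n",
    subject_id(x), gm_label(x), attr(x, "nominal_rate_hz"),
    if (is_synchronized(x)) "synchronized" else "raw (device clocks)"))
  cat(sprintf("  samples per limb: %s | span %.1f s\n",
              paste(sprintf("%s=%d", LIMB_IDS, n), collapse = " "),
              recording_duration(x)))
  NextMethod()
}

#' Read a subject's four-limb recording from disk
#'
#' Expects the on-disk layout written by [write_subject()]: one CSV per limb
#' named `<subject_id>_<limb>.csv` with header `t_s,ax,ay,az`, plus a sidecar
#' `<subject_id>.json` holding `subject_id`, `unit` (`"g"` or `"m_s2"`),
#' `nominal_rate_hz` and optional `gm_label`. Acceleration is converted to
#' m/s^2 on read (1 g = 9.80665 m/s^2). No synchronization is performed.
#'
#' @param path Directory containing the per-limb CSVs and sidecar JSON, or
#'   the path of the sidecar JSON itself.
#' @param unit Override the sidecar's declared unit (`"g"` or `"m_s2"`).
#'
#' @return A `kc_recording` (not yet synchronized).
#' @export
#' @seealso [synchronize()], [write_subject()]
read_subject <- function(path, unit = NULL) {
  if (dir.exists(path)) {
    sidecars <- list.files(path, pattern = "\\.json$", full.names = TRUE)
    if (length(sidecars) != 1) {
      format_error(sprintf("expected exactly one sidecar JSON in %s, found %d",
                           path, length(sidecars)))
    }
    sidecar <- sidecars[1]
  } else if (file.exists(path)) {
    sidecar <- path
  } else {
    format_error(sprintf("no such recording path: %s", path))
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$subject_id)) format_error("sidecar JSON lacks subject_id")
  unit <- unit %||% meta$unit %||% "m_s2"
  if (!unit %in% c("g", "m_s2")) {
    format_error(sprintf("unknown acceleration unit '%s' (expected 'g' or 'm_s2')", unit))
  }
  dirn <- dirname(sidecar)
  limbs <- lapply(LIMB_IDS, function(l) {
    f <- file.path(dirn, sprintf("%s_%s.csv", meta$subject_id, l))
    if (!file.exists(f)) missing_limb_error(l, path = f)
    d <- utils::read.csv(f)
    if (!all(c("t_s", "ax", "ay", "az") %in% names(d))) {
      format_error(sprintf("%s: expected header t_s,ax,ay,az", f))
    }
    tibble(limb = l, t_s = as.numeric(d$t_s),
           ax = as.numeric(d$ax), ay = as.numeric(d$ay), az = as.numeric(d$az))
  })
  data <- dplyr::bind_rows(limbs)
  if (unit == "g") {
    data[c("ax", "ay", "az")] <- data[c("ax", "ay", "az")] * GRAVITY_MS2
  }
  new_recording(data,
                subject_id = meta$subject_id,
                nominal_rate_hz = meta$nominal_rate_hz %||% 150,
                gm_label = (meta$gm_label %||% NA_character_) %||% NA_character_,
                pma_weeks = meta$pma_weeks %||% NA_real_,
                synchronized = FALSE)
}

#' Write a subject's recording in the package's CSV + JSON layout
#'
#' @param rec A `kc_recording`.
#' @param dir Output directory (created if needed).
#' @param unit Unit to write acceleration in (`"m_s2"`, the internal unit,
#'   or `"g"`).
#' @return Invisibly, the sidecar JSON path.
#' @export
write_subject <- function(rec, dir, unit = c("m_s2", "g")) {
  unit <- match.arg(unit)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sid <- subject_id(rec)
  for (l in LIMB_IDS) {
    d <- limb_samples(rec, l)
    if (unit == "g") d[c("ax", "ay", "az")] <- d[c("ax", "ay", "az")] / GRAVITY_MS2
    utils::write.csv(d, file.path(dir, sprintf("%s_%s.csv", sid, l)),
                     row.names = FALSE, quote = FALSE)
  }
  sidecar <- file.path(dir, paste0(sid, ".json"))
  meta <- list(subject_id = sid, unit = unit,
               nominal_rate_hz = attr(rec, "nominal_rate_hz"),
               gm_label = if (is.na(gm_label(rec))) NULL else gm_label(rec))
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(sidecar)
}
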