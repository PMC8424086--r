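#' Fit cohort range normalization for the six movement features
#'
#' The KC index normalizes each feature by its spread across all subjects of
#' the cohort: this stores, per feature, the cohort minimum and maximum whose
#' difference is the normalization denominator. The normalization is
#' cohort-dependent by construction — adding a subject can change every
#' score — so a fitted object can be frozen (see [write_normalization()])
#' and transported together with a cutoff for prospective scoring.
#'
#' @param features A feature table as returned by [extract_features()]
#'   row-bound over subjects (>= 2 rows).
#' @return A `kc_normalization` tibble with columns `feature`, `min`, `max`
#'   and attribute `n_subjects`.
#' @export
fit_normalization <- function(features) {
  stopifnot(is.data.frame(features))
  if (nrow(features) < 2) {
    degenerate_cohort_error(message = "range normalization needs at least 2 subjects")
  }
  out <- purrr::map_dfr(FEATURE_NAMES, function(f) {
    v <- features[[f]]
    if (is.null(v) || anyNA(v)) {
      format_error(sprintf("feature table lacks complete column %s", f))
    }
    tibble(feature = f, min = min(v), max = max(v))
  })
  zero <- out$feature[out$max <= out$min]
  if (length(zero) > 0) degenerate_cohort_error(zero[1])
  attr(out, "n_subjects") <- nrow(features)
  class(out) <- c("kc_normalization", class(out))
  out
}

#' Compute the KC index from features and a fitted normalization
#'
#' The score for subject *i* is
#' \deqn{KC_i = 100 \left( \sum_{l=1}^{4} \frac{kur_{i,l}}{\max(kur_l) - \min(kur_l)}
#'   + \sum_{p=1}^{2} \frac{xcorr_{i,p}}{\max(xcorr_p) - \min(xcorr_p)} \right)}
#' with equal weight on the four per-limb kurtosis terms and the two
#' inter-limb jerk cross-correlation terms. The default `"range_divide"`
#' mode divides each feature by its cohort range without subtracting the
#' cohort minimum; `"min_max"` instead maps each feature to
#' `(x - min) / (max - min)`, i.e. onto `[0, 1]` within the fitting cohort.
#' The two modes differ by a cohort-wide constant shift of every score, so
#' rankings, ROC curves and AUC are identical; cutoff values are not
#' transferable between modes.
#'
#' @param features Feature table (one row per subject).
#' @param norm A `kc_normalization` from [fit_normalization()].
#' @param mode `"range_divide"` (default) or `"min_max"`.
#' @return A tibble with `subject_id`, `kc_index`, `gm_label`, and the six
#'   normalized contributions (`contrib_*`, before the factor 100).
#' @export
compute_kc <- function(features, norm, mode = c("range_divide", "min_max")) {
  mode <- match.arg(mode)
  stopifnot(inherits(norm, "kc_normalization"))
  contrib <- purrr::map_dfc(FEATURE_NAMES, function(f) {
    r <- norm[norm$feature == f, ]
    x <- features[[f]]
    v <- if (mode == "min_max") (x - r$min) / (r$max - r$min) else x / (r$max - r$min)
    tibble("contrib_{f}" := v)
  })
  tibble(
    subject_id = features$subject_id,
    kc_index = 100 * rowSums(as.matrix(contrib)),
    gm_label = features$gm_label %||% NA_character_
  ) |>
    dplyr::bind_cols(contrib)
}

#' Score a cohort of recordings end to end
#'
#' Runs the full pipeline on each subject — synchronize, optional settling
#' trim, gravity-removing high-pass, feature extraction — then fits the
#' cohort range normalization on the subjects that survived and computes
#' every KC index against it. Subjects whose features cannot be computed
#' (e.g. a dead sensor giving a zero-variance signal) are excluded and
#' reported, not fatal.
#'
#' @param recs List of `kc_recording` objects (>= 2).
#' @param config Pipeline configuration, see [default_config()].
#' @return A list of class `kc_cohort_scores`: `scores` (tibble with
#'   `kc_index` and contributions), `features`, `normalization`, and
#'   `excluded` (tibble of `subject_id`, `reason`).
#' @export
score_cohort <- function(recs, config = default_config()) {
  config <- validate_config(config)
  res <- purrr::map(recs, function(rec) {
    tryCatch({
      if (!is_synchronized(rec)) {
        rec <- synchronize(rec, config$target_rate_hz,
                           min_duration_s = config$min_duration_s)
      }
      if (config$settle_s > 0) rec <- trim_settling(rec, config$settle_s)
      rec <- highpass(rec, cutoff_hz = config$filter$cutoff_hz,
                      order = config$filter$order,
                      zero_phase = config$filter$zero_phase)
      list(ok = TRUE, features = extract_features(rec, config$max_lag_s))
    }, kc_error = function(e) {
      list(ok = FALSE, subject_id = subject_id(rec), reason = conditionMessage(e))
    })
  })
  ok <- vapply(res, `[[`, logical(1), "ok")
  excluded <- purrr::map_dfr(res[!ok], function(r) {
    tibble(subject_id = r$subject_id, reason = r$reason)
  })
  if (sum(ok) < 2) {
    degenerate_cohort_error(message = sprintf(
      "fewer than 2 subjects scored (%d excluded); cannot fit normalization", sum(!ok)))
  }
  features <- purrr::map_dfr(res[ok], "features")
  norm <- fit_normalization(features)
  scores <- compute_kc(features, norm, mode = config$normalization)
  structure(list(scores = scores, features = features,
                 normalization = norm, excluded = excluded,
                 config = config),
            class = "kc_cohort_scores")
}

#' @export
print.kc_cohort_scores <- function(x, ...) {
  cat(sprintf("<kc_cohort_scores> %d subjects scored, %d excluded\n",
              nrow(x$scores), nrow(x$excluded)))
  s <- x$scores
  if (!all(is.na(s$gm_label))) {
    by <- dplyr::summarise(dplyr::group_by(s, .data$gm_label),
                           n = dplyr::n(),
                           mean = mean(.data$kc_index),
                           sd = stats::sd(.data$kc_index))
    print(by)
  }
  invisible(x)
}

#' @export
tidy.kc_cohort_scores <- function(x, ...) x$scores

#' @export
glance.kc_cohort_scores <- function(x, ...) {
  tibble(n_scored = nrow(x$scores), n_excluded = nrow(x$excluded),
         mean_kc = mean(x$scores$kc_index), sd_kc = stats::sd(x$scores$kc_index))
}

#' Score new subjects against a frozen normalization
#'
#' Prospective (deployment) mode: the normalization fitted on a reference
#' cohort stays frozen, so scoring a new subject does not perturb anyone
#' else's score, and a transported cutoff keeps its meaning. Optionally
#' calls each subject normal/abnormal against a cutoff.
#'
#' @param recs List of `kc_recording` objects (any length >= 1).
#' @param norm A frozen `kc_normalization`.
#' @param cutoff Optional KC-index cutoff; when given, a `call` column is
#'   added (`"Ab"` when `kc_index > cutoff`, else `"N"`).
#' @param config Pipeline configuration.
#' @return A tibble like [compute_kc()]'s, plus `call` when `cutoff` given.
#' @export
classify_subjects <- function(recs, norm, cutoff = NULL, config = default_config()) {
  config <- validate_config(config)
  features <- purrr::map_dfr(recs, function(rec) {
    if (!is_synchronized(rec)) {
      rec <- synchronize(rec, config$target_rate_hz,
                         min_duration_s = config$min_duration_s)
    }
    if (config$settle_s > 0) rec <- trim_settling(rec, config$settle_s)
    rec <- highpass(rec, cutoff_hz = config$filter$cutoff_hz,
                    order = config$filter$order,
                    zero_phase = config$filter$zero_phase)
    extract_features(rec, config$max_lag_s)
  })
  out <- compute_kc(features, norm, mode = config$normalization)
  if (!is.null(cutoff)) {
    out$call <- ifelse(out$kc_index > cutoff, "Ab", "N")
  }
  out
}

#' Freeze / restore a cohort normalization as JSON
#'
#' @param norm A `kc_normalization`.
#' @param path JSON file path.
#' @param config Optional pipeline config; its hash is embedded so a cutoff
#'   travels with the settings it was derived under.
#' @return `write_normalization()` the path, invisibly;
#'   `read_normalization()` a `kc_normalization`.
#' @export
write_normalization <- function(norm, path, config = NULL) {
  stopifnot(inherits(norm, "kc_normalization"))
  per <- lapply(seq_len(nrow(norm)), function(i) {
    list(min = norm$min[i], max = norm$max[i])
  })
  names(per) <- norm$feature
  obj <- list(features = per,
              n_subjects = attr(norm, "n_subjects"),
              config_hash = if (!is.null(config)) config_hash(config) else NULL,
              package_version = as.character(utils::packageVersion("kcindex")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_normalization
#' @export
read_normalization <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- purrr::map_dfr(FEATURE_NAMES, function(f) {
    e <- obj$features[[f]]
    if (is.null(e)) format_error(sprintf("normalization JSON lacks feature %s", f))
    tibble(feature = f, min = e$min, max = e$max)
  })
  attr(out, "n_subjects") <- obj$n_subjects
  attr(out, "config_hash") <- obj$config_hash
  class(out) <- c("kc_normalization", class(out))
  out
}
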