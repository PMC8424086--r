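#' Pipeline configuration
#'
#' One list gathering every tunable of the scoring pipeline, with defaults
#' reproducing the standard acquisition and analysis settings: 150 Hz
#' sampling, 10-minute recordings, 0.05 Hz gravity high-pass, +/-2 s jerk
#' cross-correlation lag window, 1000 bootstrap resamples.
#'
#' @param ... Named overrides of any default (nested lists are merged).
#' @return A validated config list of class `kc_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    target_rate_hz = 150,
    min_duration_s = 600,
    settle_s = 0,
    filter = list(cutoff_hz = 0.05, order = 4, zero_phase = TRUE),
    max_lag_s = 2,
    kurtosis_convention = "pearson_biased",
    normalization = "range_divide",
    n_boot = 1000,
    seed = 1,
    positive_labels = c("PR", "CS")
  )
  over <- list(...)
  if (length(over) > 0) cfg <- utils::modifyList(cfg, over)
  validate_config(cfg)
}

#' @rdname default_config
#' @param config A (possibly partial) config list; missing entries are
#'   filled with defaults, every entry is checked.
#' @export
validate_config <- function(config) {
  if (inherits(config, "kc_config")) return(config)
  if (!is.list(config)) format_error("config must be a list")
  cfg <- list(
    target_rate_hz = 150, min_duration_s = 600, settle_s = 0,
    filter = list(cutoff_hz = 0.05, order = 4, zero_phase = TRUE),
    max_lag_s = 2, kurtosis_convention = "pearson_biased",
    normalization = "range_divide", n_boot = 1000, seed = 1,
    positive_labels = c("PR", "CS")
  )
  cfg <- utils::modifyList(cfg, config)
  ok <- function(cond, msg) if (!cond) format_error(paste("config:", msg))
  ok(is.numeric(cfg$target_rate_hz) && cfg$target_rate_hz > 0,
     "target_rate_hz must be a positive number")
  ok(is.numeric(cfg$min_duration_s) && cfg$min_duration_s > 0,
     "min_duration_s must be positive")
  ok(is.numeric(cfg$settle_s) && cfg$settle_s >= 0, "settle_s must be >= 0")
  ok(is.numeric(cfg$filter$cutoff_hz) && cfg$filter$cutoff_hz > 0 &&
       cfg$filter$cutoff_hz < cfg$target_rate_hz / 2,
     "filter.cutoff_hz must lie in (0, target_rate_hz/2)")
  ok(is.numeric(cfg$filter$order) && cfg$filter$order >= 1,
     "filter.order must be >= 1")
  ok(is.logical(cfg$filter$zero_phase), "filter.zero_phase must be true/false")
  ok(is.numeric(cfg$max_lag_s) && cfg$max_lag_s >= 0, "max_lag_s must be >= 0")
  ok(identical(cfg$kurtosis_convention, "pearson_biased"),
     "kurtosis_convention is fixed to 'pearson_biased' (recorded for provenance)")
  ok(cfg$normalization %in% c("range_divide", "min_max"),
     "normalization must be 'range_divide' or 'min_max'")
  ok(is.numeric(cfg$n_boot) && cfg$n_boot >= 1, "n_boot must be >= 1")
  ok(all(cfg$positive_labels %in% c(GM_LABELS, "Ab")) &&
       length(cfg$positive_labels) >= 1,
     "positive_labels must be drawn from N, PR, CS, Ab")
  class(cfg) <- c("kc_config", "list")
  cfg
}

#' @rdname default_config
#' @param path JSON file holding (a subset of) the config fields.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) format_error(sprintf("config file not found: %s", path))
  validate_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname default_config
#' @export
config_hash <- function(config) {
  cfg <- validate_config(config)
  rlang::hash(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA))
}
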