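# Classed conditions so callers can test failure modes programmatically.
# All inherit from "kc_error".

kc_abort <- function(class, message, ...) {
  abort(message, class = c(class, "kc_error"), ...)
}

missing_limb_error <- function(limb, path = NULL) {
  kc_abort("kc_missing_limb_error",
           sprintf("recording for limb %s is missing", limb),
           limb = limb, path = path)
}

format_error <- function(message, ...) {
  kc_abort("kc_format_error", message, ...)
}

insufficient_overlap_error <- function(overlap_s, required_s) {
  kc_abort("kc_insufficient_overlap_error",
           sprintf("limb time spans overlap for %.2f s; at least %.2f s required",
                   overlap_s, required_s),
           overlap_s = overlap_s, required_s = required_s)
}

empty_recording_error <- function(message) {
  kc_abort("kc_empty_recording_error", message)
}

not_synchronized_error <- function(what) {
  kc_abort("kc_not_synchronized_error",
           sprintf("%s requires a synchronized recording on a uniform grid; run synchronize() first",
                   what))
}

degenerate_signal_error <- function(where) {
  kc_abort("kc_degenerate_signal_error",
           sprintf("degenerate (zero-variance or too-short) signal in %s", where),
           where = where)
}

degenerate_cohort_error <- function(feature = NULL, message = NULL) {
  msg <- message %||%
    sprintf("cohort range is zero for feature %s; range normalization undefined", feature)
  kc_abort("kc_degenerate_cohort_error", msg, feature = feature)
}

degenerate_labels_error <- function(message) {
  kc_abort("kc_degenerate_labels_error", message)
}
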