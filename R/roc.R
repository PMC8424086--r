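#' ROC curve and AUC for a scored, labelled cohort
#'
#' Subjects with an abnormal general-movement pattern (poor repertoire or
#' cramped synchronized; the positive class) are expected to score high on
#' the KC index, so a subject is predicted abnormal when its score exceeds a
#' threshold (strictly). Candidate thresholds are the midpoints between
#' consecutive distinct sorted scores plus -Inf/+Inf sentinels; the AUC is
#' the trapezoidal area under the resulting curve, which equals the
#' Mann-Whitney probability of concordance with ties counted 1/2.
#'
#' @param data Data frame with one row per subject.
#' @param score Column holding the score (tidy-eval; default `kc_index`).
#' @param label Column holding the class label (default `gm_label`).
#' @param positive Label values forming the positive (abnormal) class;
#'   default `c("PR", "CS", "Ab")`.
#' @return A `kc_roc` object: `points` (tibble of `threshold`,
#'   `sensitivity`, `specificity`), `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(data, score = kc_index, label = gm_label,
                      positive = c("PR", "CS", "Ab")) {
  s <- dplyr::pull(data, {{ score }})
  l <- dplyr::pull(data, {{ label }})
  pos <- as.character(l) %in% positive
  check_labeled_scores(s, pos)
  r <- roc_points(s, pos)
  structure(list(points = r, auc = trapezoid_auc(r),
                 n_pos = sum(pos), n_neg = sum(!pos)),
            class = "kc_roc")
}

check_labeled_scores <- function(s, pos) {
  if (anyNA(s) || any(!is.finite(s))) {
    format_error("scores must be finite and non-missing")
  }
  if (all(pos) || all(!pos)) {
    degenerate_labels_error("need at least one positive and one negative subject")
  }
  invisible(TRUE)
}

# Operating points over midpoint thresholds (plus sentinels), prediction
# rule: positive when score > threshold.
roc_points <- function(s, pos) {
  v <- sort(unique(s))
  thr <- c(-Inf, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2, Inf)
  sp <- s[pos]; sn <- s[!pos]
  tibble(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(sp > t), numeric(1)),
    specificity = vapply(thr, function(t) mean(sn <= t), numeric(1))
  )
}

trapezoid_auc <- function(points) {
  x <- 1 - points$specificity
  y <- points$sensitivity
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Youden-optimal cutoff of a ROC curve
#'
#' Chooses the threshold maximizing Youden's J = sensitivity +
#' specificity - 1. Ties are broken in favour of higher specificity, then
#' of the lower threshold value, making the choice deterministic.
#'
#' @param roc A `kc_roc` from [roc_curve()].
#' @return One-row tibble: `cutoff`, `sensitivity`, `specificity`, `youden_j`.
#' @export
youden_cutoff <- function(roc) {
  p <- if (inherits(roc, "kc_roc")) roc$points else roc
  finite <- is.finite(p$threshold)
  p <- if (any(finite)) p[finite, ] else p
  j <- p$sensitivity + p$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[order(-p$specificity[best], p$threshold[best])][1]
  tibble(cutoff = p$threshold[best],
         sensitivity = p$sensitivity[best],
         specificity = p$specificity[best],
         youden_j = j[best])
}

# Draw bootstrap resample index sets; resamples that lose one of the two
# classes are redrawn (so every resample supports a ROC), with the number of
# redraws reported. Stratified mode resamples within class instead.
resample_indices <- function(pos, n_boot, stratified = FALSE) {
  n <- length(pos)
  out <- vector("list", n_boot)
  redraws <- 0L
  if (stratified) {
    ip <- which(pos); ineg <- which(!pos)
    for (b in seq_len(n_boot)) {
      out[[b]] <- c(sample(ip, length(ip), replace = TRUE),
                    sample(ineg, length(ineg), replace = TRUE))
    }
  } else {
    max_draws <- 100 * n_boot
    draws <- 0L
    b <- 1L
    while (b <= n_boot) {
      if (draws >= max_draws) {
        degenerate_labels_error(sprintf(
          "bootstrap failed to draw two-class resamples after %d attempts", draws))
      }
      idx <- sample.int(n, n, replace = TRUE)
      draws <- draws + 1L
      if (all(pos[idx]) || all(!pos[idx])) {
        redraws <- redraws + 1L
        next
      }
      out[[b]] <- idx
      b <- b + 1L
    }
  }
  attr(out, "redraws") <- redraws
  out
}

boot_percentile_ci <- function(s, pos, n_boot, seed, statistic,
                               stratified = FALSE, level = 0.95) {
  with_preserved_seed({
    set.seed(seed)
    idx <- resample_indices(pos, n_boot, stratified)
    stats <- vapply(idx, function(i) statistic(s[i], pos[i]), numeric(1))
    ci <- unname(quantile(stats, c((1 - level) / 2, 1 - (1 - level) / 2), type = 7))
    list(lo = ci[1], hi = ci[2], stats = stats, redraws = attr(idx, "redraws"))
  })
}

with_preserved_seed <- function(code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  force(code)
}

#' Percentile-bootstrap confidence interval for the Youden cutoff
#'
#' Draws `n_boot` resamples with replacement of the (score, label) pairs,
#' of the same size as the original data (unstratified by default);
#' recomputes the ROC and its Youden-optimal cutoff on each resample; and
#' takes the 2.5th and 97.5th percentiles of the resampled cutoffs.
#' Resamples in which one class is absent are redrawn and counted.
#'
#' @inheritParams roc_curve
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed RNG seed for the resampling.
#' @param stratified Resample within class instead (default `FALSE`).
#' @param level Confidence level (default 0.95).
#' @return One-row tibble: `lo`, `hi`, `n_boot`, `redraws`.
#' @export
bootstrap_cutoff_ci <- function(data, score = kc_index, label = gm_label,
                                positive = c("PR", "CS", "Ab"),
                                n_boot = 1000, seed = 1,
                                stratified = FALSE, level = 0.95) {
  s <- dplyr::pull(data, {{ score }})
  pos <- as.character(dplyr::pull(data, {{ label }})) %in% positive
  check_labeled_scores(s, pos)
  r <- boot_percentile_ci(s, pos, n_boot, seed, function(si, pi) {
    youden_cutoff(structure(list(points = roc_points(si, pi)), class = "kc_roc"))$cutoff
  }, stratified = stratified, level = level)
  tibble(lo = r$lo, hi = r$hi, n_boot = n_boot, redraws = r$redraws)
}

#' Percentile-bootstrap confidence interval for the AUC
#'
#' Same resampling engine as [bootstrap_cutoff_ci()], with the AUC as the
#' per-resample statistic.
#'
#' @inheritParams bootstrap_cutoff_ci
#' @return One-row tibble: `lo`, `hi`, `n_boot`, `redraws`.
#' @export
auc_ci <- function(data, score = kc_index, label = gm_label,
                   positive = c("PR", "CS", "Ab"),
                   n_boot = 1000, seed = 1, stratified = FALSE, level = 0.95) {
  s <- dplyr::pull(data, {{ score }})
  pos <- as.character(dplyr::pull(data, {{ label }})) %in% positive
  check_labeled_scores(s, pos)
  r <- boot_percentile_ci(s, pos, n_boot, seed, function(si, pi) {
    trapezoid_auc(roc_points(si, pi))
  }, stratified = stratified, level = level)
  tibble(lo = r$lo, hi = r$hi, n_boot = n_boot, redraws = r$redraws)
}

#' Full discrimination analysis of a scored cohort
#'
#' Combines [roc_curve()], [youden_cutoff()], [auc_ci()] and
#' [bootstrap_cutoff_ci()] into one fitted object with [tidy()], [glance()]
#' and [autoplot()] methods.
#'
#' @inheritParams bootstrap_cutoff_ci
#' @return A `kc_roc_result` object.
#' @export
#' @examples
#' scores <- tibble::tibble(
#'   kc_index = c(rnorm(20, 180, 25), rnorm(10, 240, 30)),
#'   gm_label = rep(c("N", "PR"), c(20, 10)))
#' fit <- evaluate_scores(scores, n_boot = 100, seed = 42)
#' glance(fit)
evaluate_scores <- function(data, score = kc_index, label = gm_label,
                            positive = c("PR", "CS", "Ab"),
                            n_boot = 1000, seed = 1, stratified = FALSE,
                            level = 0.95) {
  roc <- roc_curve(data, {{ score }}, {{ label }}, positive = positive)
  yc <- youden_cutoff(roc)
  aci <- auc_ci(data, {{ score }}, {{ label }}, positive = positive,
                n_boot = n_boot, seed = seed, stratified = stratified,
                level = level)
  cci <- bootstrap_cutoff_ci(data, {{ score }}, {{ label }}, positive = positive,
                             n_boot = n_boot, seed = seed,
                             stratified = stratified, level = level)
  structure(list(
    roc = roc, auc = roc$auc, auc_ci = c(lo = aci$lo, hi = aci$hi),
    cutoff = yc$cutoff, cutoff_ci = c(lo = cci$lo, hi = cci$hi),
    sens_at_cutoff = yc$sensitivity, spec_at_cutoff = yc$specificity,
    youden_j = yc$youden_j,
    n_pos = roc$n_pos, n_neg = roc$n_neg,
    n_boot = n_boot, seed = seed, stratified = stratified, level = level,
    redraws = c(auc = aci$redraws, cutoff = cci$redraws)
  ), class = "kc_roc_result")
}

#' @export
print.kc_roc_result <- function(x, ...) {
  cat(sprintf("<kc_roc_result> %d positive / %d negative subjects\n", x$n_pos, x$n_neg))
  cat(sprintf("  AUC %.3f (%.0f%% CI %.3f-%.3f)\n", x$auc, 100 * x$level,
              x$auc_ci["lo"], x$auc_ci["hi"]))
  cat(sprintf("  Youden cutoff %.2f (%.0f%% bootstrap CI %.2f-%.2f), sens %.2f / spec %.2f\n",
              x$cutoff, 100 * x$level, x$cutoff_ci["lo"], x$cutoff_ci["hi"],
              x$sens_at_cutoff, x$spec_at_cutoff))
  invisible(x)
}

#' @export
tidy.kc_roc <- function(x, ...) x$points

#' @export
tidy.kc_roc_result <- function(x, ...) x$roc$points

#' @export
glance.kc_roc <- function(x, ...) {
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @export
glance.kc_roc_result <- function(x, ...) {
  tibble(auc = x$auc,
         auc_ci_lo = unname(x$auc_ci["lo"]), auc_ci_hi = unname(x$auc_ci["hi"]),
         cutoff = x$cutoff,
         cutoff_ci_lo = unname(x$cutoff_ci["lo"]),
         cutoff_ci_hi = unname(x$cutoff_ci["hi"]),
         sensitivity = x$sens_at_cutoff, specificity = x$spec_at_cutoff,
         youden_j = x$youden_j,
         n_pos = x$n_pos, n_neg = x$n_neg, n_boot = x$n_boot, seed = x$seed)
}

#' @rdname evaluate_scores
#' @param object A `kc_roc` or `kc_roc_result`.
#' @param ... Unused.
#' @export
autoplot.kc_roc_result <- function(object, ...) {
  p <- tidy(object)
  at <- youden_cutoff(object$roc)
  ggplot2::ggplot(p, ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted", colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::annotate("point", x = 1 - at$specificity, y = at$sensitivity,
                      shape = 21, size = 3) +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("ROC: AUC = %.2f, Youden cutoff = %.1f", object$auc, object$cutoff)
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @export
autoplot.kc_roc <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted", colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("ROC: AUC = %.2f", object$auc)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Distribution of KC-index scores by clinical group
#'
#' Jittered strip plot of per-subject scores by group, with an optional
#' horizontal cutoff line — the package's analogue of the classic
#' score-by-group figure.
#'
#' @param scores Tibble with `kc_index` and `gm_label`.
#' @param cutoff Optional cutoff to draw as a dashed line.
#' @return A ggplot object.
#' @export
plot_kc_distribution <- function(scores, cutoff = NULL) {
  p <- ggplot2::ggplot(scores, ggplot2::aes(x = .data$gm_label, y = .data$kc_index)) +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3, colour = "black") +
    ggplot2::labs(x = "Clinical GM group", y = "KC index") +
    ggplot2::theme_minimal()
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed")
  }
  p
}
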