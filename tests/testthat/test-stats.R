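labeled <- function(scores, pos) {
  tibble::tibble(kc_index = scores,
                 gm_label = ifelse(pos, "Ab", "N"))
}

test_that("AUC hits the closed-form corner cases", {
  perfect <- labeled(c(10, 9, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(roc_curve(perfect)$auc, 1.0)
  exchangeable <- labeled(c(1, 2, 3, 1, 2, 3), rep(c(TRUE, FALSE), each = 3))
  expect_equal(roc_curve(exchangeable)$auc, 0.5)
  expect_error(roc_curve(labeled(1:4, rep(TRUE, 4))),
               class = "kc_degenerate_labels_error")
})

test_that("AUC equals the concordant-pair oracle on random instances", {
  withr::local_seed(101)
  for (i in 1:40) {
    n <- sample(5:50, 1)
    s <- round(rnorm(n, 200, 30), sample(c(0, 1, 2), 1))  # induce ties
    pos <- runif(n) < 0.4
    if (all(pos) || all(!pos)) next
    d <- labeled(s, pos)
    expect_equal(roc_curve(d)$auc, auc_pairwise_oracle(s, pos),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with pROC", {
  skip_if_not_installed("pROC")
  withr::local_seed(102)
  s <- rnorm(60, 200, 30); pos <- runif(60) < 0.4
  d <- labeled(s, pos)
  ref <- suppressMessages(pROC::auc(pROC::roc(response = pos, predictor = s,
                                              direction = "<", quiet = TRUE)))
  expect_equal(roc_curve(d)$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("operating points are monotone in the threshold", {
  withr::local_seed(103)
  d <- labeled(rnorm(40, 200, 30), runif(40) < 0.5)
  p <- roc_curve(d)$points
  expect_true(all(diff(p$sensitivity) <= 1e-12))
  expect_true(all(diff(p$specificity) >= -1e-12))
})

test_that("Youden cutoff matches closed forms and the exhaustive scan", {
  perfect <- labeled(c(10, 9, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  yc <- youden_cutoff(roc_curve(perfect))
  expect_equal(yc$cutoff, 5.5)  # midpoint between the classes
  expect_equal(yc$sensitivity, 1)
  expect_equal(yc$specificity, 1)
  three <- labeled(c(3, 1, 2), c(TRUE, FALSE, FALSE))
  yc3 <- youden_cutoff(roc_curve(three))
  expect_equal(yc3$cutoff, 2.5)
  expect_equal(yc3$sensitivity, 1)
  expect_equal(yc3$specificity, 1)
  withr::local_seed(104)
  for (i in 1:30) {
    n <- sample(6:50, 1)
    s <- round(rnorm(n, 200, 30), 1)
    pos <- runif(n) < 0.5
    if (all(pos) || all(!pos)) next
    yc <- youden_cutoff(roc_curve(labeled(s, pos)))
    oracle <- youden_scan_oracle(s, pos)
    expect_equal(yc$cutoff, oracle$cutoff, tolerance = 1e-12)
    expect_equal(yc$youden_j, oracle$j, tolerance = 1e-12)
  }
})

test_that("swapping the class definition mirrors the AUC", {
  withr::local_seed(105)
  s <- rnorm(30, 0, 1); pos <- runif(30) < 0.5
  a1 <- roc_curve(labeled(s, pos))$auc
  a2 <- roc_curve(labeled(s, !pos))$auc
  expect_equal(a1 + a2, 1, tolerance = 1e-12)
})

test_that("shifting all scores shifts the cutoff, not AUC or sens/spec", {
  withr::local_seed(106)
  s <- rnorm(40, 200, 30); pos <- runif(40) < 0.4
  f1 <- evaluate_scores(labeled(s, pos), n_boot = 50, seed = 7)
  f2 <- evaluate_scores(labeled(s + 55, pos), n_boot = 50, seed = 7)
  expect_equal(f2$auc, f1$auc, tolerance = 1e-12)
  expect_equal(f2$cutoff, f1$cutoff + 55, tolerance = 1e-9)
  expect_equal(f2$sens_at_cutoff, f1$sens_at_cutoff, tolerance = 1e-12)
  expect_equal(f2$spec_at_cutoff, f1$spec_at_cutoff, tolerance = 1e-12)
})

test_that("bootstrap CIs are deterministic under a fixed seed", {
  withr::local_seed(107)
  d <- labeled(rnorm(40, 200, 30), runif(40) < 0.4)
  c1 <- bootstrap_cutoff_ci(d, n_boot = 100, seed = 11)
  c2 <- bootstrap_cutoff_ci(d, n_boot = 100, seed = 11)
  expect_identical(c1, c2)
  a1 <- auc_ci(d, n_boot = 100, seed = 11)
  a2 <- auc_ci(d, n_boot = 100, seed = 11)
  expect_identical(a1, a2)
})

test_that("zero-variance resamples collapse the cutoff CI to a point", {
  # two well-separated score plateaus: every two-class resample has the
  # same midpoint cutoff
  d <- labeled(c(rep(10, 6), rep(0, 6)), rep(c(TRUE, FALSE), each = 6))
  ci <- bootstrap_cutoff_ci(d, n_boot = 100, seed = 3)
  expect_equal(ci$lo, 5)
  expect_equal(ci$hi, 5)
  aci <- auc_ci(d, n_boot = 100, seed = 3)
  expect_equal(aci$lo, 1)
  expect_equal(aci$hi, 1)
})

test_that("one-class resamples are redrawn and counted", {
  d <- labeled(c(5, 1, 1.5, 2, 2.5, 3), c(TRUE, rep(FALSE, 5)))
  ci <- bootstrap_cutoff_ci(d, n_boot = 200, seed = 5)
  expect_gt(ci$redraws, 0)  # P(losing the single positive) = (5/6)^6 ~ 0.33
  expect_true(is.finite(ci$lo) && ci$lo <= ci$hi)
})

test_that("the full-data AUC lies inside its bootstrap CI", {
  withr::local_seed(108)
  d <- labeled(c(rnorm(30, 200, 25), rnorm(15, 240, 25)),
               rep(c(FALSE, TRUE), c(30, 15)))
  fit <- evaluate_scores(d, n_boot = 300, seed = 13)
  expect_gte(fit$auc, fit$auc_ci["lo"] - 1e-12)
  expect_lte(fit$auc, fit$auc_ci["hi"] + 1e-12)
  expect_gte(fit$cutoff, fit$cutoff_ci["lo"] - 1e-12)
  expect_lte(fit$cutoff, fit$cutoff_ci["hi"] + 1e-12)
})

test_that("cutoff CI width shrinks as the cohort grows", {
  width_at <- function(n, seed) {
    withr::with_seed(seed, {
      d <- labeled(c(rnorm(2 * n, 200, 25), rnorm(n, 245, 25)),
                   rep(c(FALSE, TRUE), c(2 * n, n)))
    })
    ci <- bootstrap_cutoff_ci(d, n_boot = 150, seed = seed)
    ci$hi - ci$lo
  }
  small <- sapply(1:8, function(s) width_at(15, 300 + s))
  big <- sapply(1:8, function(s) width_at(60, 400 + s))
  expect_lt(mean(big), mean(small))
})

test_that("bootstrap AUC CI is compatible with the DeLong interval", {
  skip_if_not_installed("pROC")
  withr::local_seed(109)
  d <- labeled(c(rnorm(35, 200, 25), rnorm(20, 235, 25)),
               rep(c(FALSE, TRUE), c(35, 20)))
  ours <- auc_ci(d, n_boot = 500, seed = 17)
  dl <- suppressMessages(pROC::ci.auc(pROC::roc(
    response = d$gm_label == "Ab", predictor = d$kc_index,
    direction = "<", quiet = TRUE), method = "delong"))
  # same quantity, different CI machinery: intervals must overlap
  expect_lt(max(ours$lo, dl[1]), min(ours$hi, dl[3]))
})

test_that("stratified resampling preserves the class split", {
  d <- labeled(c(5, 6, 7, 1, 2, 3, 3.5, 4), c(rep(TRUE, 3), rep(FALSE, 5)))
  ci <- bootstrap_cutoff_ci(d, n_boot = 100, seed = 19, stratified = TRUE)
  expect_identical(ci$redraws, 0L)
  expect_true(is.finite(ci$lo) && is.finite(ci$hi))
})

test_that("evaluate_scores tidies and glances", {
  withr::local_seed(110)
  d <- labeled(c(rnorm(20, 200, 25), rnorm(10, 240, 25)),
               rep(c(FALSE, TRUE), c(20, 10)))
  fit <- evaluate_scores(d, n_boot = 50, seed = 23)
  td <- tidy(fit)
  expect_true(all(c("threshold", "sensitivity", "specificity") %in% names(td)))
  g <- glance(fit)
  expect_identical(nrow(g), 1L)
  expect_true(g$auc >= 0 && g$auc <= 1)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
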