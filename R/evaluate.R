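#' Binarise continuous scores at a fixed decision threshold
#'
#' A score strictly below the threshold predicts CAD negative; otherwise
#' (including exact equality) CAD positive.
#'
#' @param scores Finite numeric scores.
#' @param threshold Decision cutoff.
#' @return Integer vector of 0/1 predictions.
#' @export
classify_scores <- function(scores, threshold) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  as.integer(scores >= threshold)
}

#' Confusion matrix and diagnostic metrics
#'
#' Standard formulas: sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' NPV = TN/(TN+FN), PPV = TP/(TP+FP). A metric whose denominator is zero
#' is reported as `NA` (absent), never as 0, and no error is raised.
#'
#' @param predictions Binary predictions (0/1).
#' @param labels Binary reference labels.
#' @return A list of class `confusion_metrics` with `tp`, `fp`, `tn`, `fn`,
#'   `n`, `sensitivity`, `specificity`, `npv`, `ppv`.
#' @export
confusion_metrics <- function(predictions, labels) {
  predictions <- .as_binary(predictions)
  labels <- .as_binary(labels)
  if (length(predictions) != length(labels))
    stop("predictions and labels lengths differ")
  tp <- sum(predictions == 1 & labels == 1)
  fp <- sum(predictions == 1 & labels == 0)
  tn <- sum(predictions == 0 & labels == 0)
  fn <- sum(predictions == 0 & labels == 1)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, n = tp + fp + tn + fn,
                 sensitivity = ratio(tp, tp + fn),
                 specificity = ratio(tn, tn + fp),
                 npv = ratio(tn, tn + fn),
                 ppv = ratio(tp, tp + fp)),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("Confusion matrix (n = %d): TP %d, FP %d, TN %d, FN %d\n",
              x$n, x$tp, x$fp, x$tn, x$fn))
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", 100 * v)
  cat(sprintf("  sensitivity %s, specificity %s, NPV %s, PPV %s\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$npv), fmt(x$ppv)))
  invisible(x)
}

#' Select the clinical decision threshold from validation ROC points
#'
#' Scans every ROC operating point of the validation scores and returns,
#' among points with sensitivity >= `sens_floor`, the threshold maximising
#' specificity; ties are broken toward higher sensitivity and then toward
#' the lower threshold. Each operating point is represented by the midpoint
#' of the score interval realising it (the usual ROC-threshold convention).
#' The threshold is chosen on validation data only and
#' frozen before verification. If no operating point reaches the floor, the
#' point of maximal sensitivity is returned with a warning (attribute
#' `floor_met = FALSE`).
#'
#' @param scores Continuous validation scores.
#' @param labels Binary validation labels (both classes required).
#' @param sens_floor Minimum acceptable sensitivity (default 0.90, the
#'   safety-first operating rule).
#' @return The threshold, with attributes `sensitivity`, `specificity`,
#'   `floor_met`.
#' @export
select_threshold <- function(scores, labels, sens_floor = 0.90) {
  labels <- .as_binary(labels)
  if (!any(labels == 1) || !any(labels == 0))
    stop("both classes must be present in the validation set")
  # every ROC operating point, represented by the midpoint of the score
  # interval that realises it (the lowest-threshold convention, maximising
  # the margin to the scores on either side); the end candidates give the
  # all-positive and all-negative rules
  us <- sort(unique(scores))
  cand <- c(us[1] - 1,
            if (length(us) > 1) (us[-1] + us[-length(us)]) / 2,
            us[length(us)] + 1)
  stats <- vapply(cand, function(t) {
    cm <- confusion_metrics(classify_scores(scores, t), labels)
    c(cm$sensitivity, cm$specificity)
  }, numeric(2))
  sens <- stats[1, ]; spec <- stats[2, ]
  ok <- sens >= sens_floor
  floor_met <- any(ok)
  if (!floor_met) {
    warning(sprintf("no operating point reaches sensitivity %.2f; %s",
                    sens_floor, "returning the maximal-sensitivity point"))
    ok <- sens == max(sens)
  }
  idx <- which(ok)
  idx <- idx[order(-spec[idx], -sens[idx], cand[idx])][1]
  structure(cand[idx], sensitivity = sens[idx], specificity = spec[idx],
            floor_met = floor_met)
}

#' BCa bootstrap confidence interval for a diagnostic metric
#'
#' Subject-level resampling with replacement; the interval is
#' bias-corrected and accelerated (BCa), with the acceleration estimated by
#' jackknife. The bias-correction quantile counts ties as one half, so a
#' degenerate (zero-variance) statistic collapses the interval onto the
#' point estimate. Resamples for which the metric is undefined (e.g. a
#' sensitivity resample containing no positives) are skipped and counted;
#' more than 50% degenerate resamples is an error advising a larger cohort.
#'
#' @param stat_fn Function `(x, labels) -> scalar` (may return `NA` for a
#'   degenerate resample), e.g.
#'   `function(p, l) confusion_metrics(p, l)$sensitivity`, or an AUC of
#'   continuous scores via [rank_auc()].
#' @param x Predictions or scores, resampled jointly with `labels`.
#' @param labels Binary reference labels.
#' @param n_boot Number of bootstrap resamples.
#' @param level Confidence level.
#' @param seed Optional integer seed (identical seed, identical interval).
#' @return Length-2 vector `(low, high)` with attributes `point`, `n_boot`,
#'   `n_degenerate`, `z0`, `acceleration`. The interval always brackets the
#'   point estimate.
#' @export
bootstrap_ci <- function(stat_fn, x, labels, n_boot = 2000L, level = 0.95,
                         seed = NULL) {
  n <- length(x)
  if (n < 2) stop("at least 2 subjects are required")
  if (length(labels) != n) stop("x and labels lengths differ")
  theta <- stat_fn(x, labels)
  if (is.na(theta)) stop("the metric is undefined on the full sample")
  if (!is.null(seed)) set.seed(seed)
  th <- vapply(seq_len(n_boot), function(b) {
    s <- sample.int(n, replace = TRUE)
    stat_fn(x[s], labels[s])
  }, numeric(1))
  n_deg <- sum(is.na(th))
  if (n_deg > n_boot / 2)
    stop("more than half of the bootstrap resamples left the metric ",
         "undefined; a larger cohort is needed")
  th <- th[!is.na(th)]

  # bias correction with ties counted one half
  z0 <- qnorm((sum(th < theta) + 0.5 * sum(th == theta)) / length(th))
  # jackknife acceleration
  ji <- vapply(seq_len(n), function(i) stat_fn(x[-i], labels[-i]), numeric(1))
  ji <- ji[!is.na(ji)]
  num <- sum((mean(ji) - ji)^3)
  den <- 6 * sum((mean(ji) - ji)^2)^1.5
  a <- if (is.finite(num / den)) num / den else 0

  zl <- qnorm((1 - level) / 2); zu <- -zl
  adj <- function(z) pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  probs <- c(adj(zl), adj(zu))
  probs[is.na(probs)] <- c(0, 1)[is.na(probs)]
  ci <- unname(quantile(th, probs, names = FALSE, type = 7))
  # the interval must bracket the point estimate
  ci <- c(min(ci[1], theta), max(ci[2], theta))
  structure(ci, point = theta, n_boot = n_boot, n_degenerate = n_deg,
            z0 = z0, acceleration = a)
}

#' Pooled-variance two-sample t-test from summary statistics
#'
#' Two-sided Student test with the pooled variance estimate, computable from
#' printed (mean, sd, n) summaries alone -- the form that reproduces a
#' published demographics table row without raw data.
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @return List with `t`, `df`, `p_value`.
#' @examples
#' ttest_summary(61.5, 10.7, 512, 59.0, 9.8, 94)$p_value  # ~0.035
#' @export
ttest_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tt <- if (se == 0) 0 else (mean1 - mean2) / se
  df <- n1 + n2 - 2
  list(t = tt, df = df, p_value = 2 * pt(-abs(tt), df))
}

#' Chi-square test of two proportions from counts
#'
#' Pearson chi-square (no continuity correction) on the 2 x 2 table of
#' event counts, as used for the categorical rows of a demographics table.
#'
#' @param x1,n1 Events and total in group 1.
#' @param x2,n2 Events and total in group 2.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chisq_counts <- function(x1, n1, x2, n2) {
  tab <- rbind(c(x1, n1 - x1), c(x2, n2 - x2))
  if (any(tab < 0)) stop("counts must be nonnegative and <= n")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = if (is.nan(res$p.value)) 1 else unname(res$p.value))
}

#' Demographics comparison table between two cohorts
#'
#' Continuous variables are compared by the pooled-variance two-sample
#' t-test, categorical variables by the Pearson chi-square test on the
#' 2 x 2 counts, mirroring a study's Table-1-style comparison of the
#' development and verification cohorts.
#'
#' @param group_a,group_b Subject data frames with columns `age`,
#'   `heart_rate`, `bmi` (continuous), `sex` (`"male"`/`"female"`) and
#'   `cad_label` (0/1).
#' @return Data frame with one row per variable: group summaries, the full
#'   precision `p_value` and the 2-decimal `p_rounded` used for display.
#' @export
demographic_table <- function(group_a, group_b) {
  rows <- list()
  for (v in c("age", "bmi", "heart_rate")) {
    tt <- ttest_summary(mean(group_a[[v]]), sd(group_a[[v]]), nrow(group_a),
                        mean(group_b[[v]]), sd(group_b[[v]]), nrow(group_b))
    rows[[v]] <- data.frame(
      variable = v, type = "continuous",
      group_a = sprintf("%.1f ± %.1f", mean(group_a[[v]]),
                        sd(group_a[[v]])),
      group_b = sprintf("%.1f ± %.1f", mean(group_b[[v]]),
                        sd(group_b[[v]])),
      p_value = tt$p_value)
  }
  cats <- list(male = function(d) sum(d$sex == "male"),
               cad_positive = function(d) sum(d$cad_label == 1))
  for (v in names(cats)) {
    xa <- cats[[v]](group_a); xb <- cats[[v]](group_b)
    ct <- chisq_counts(xa, nrow(group_a), xb, nrow(group_b))
    rows[[v]] <- data.frame(
      variable = v, type = "categorical",
      group_a = sprintf("%.1f%%", 100 * xa / nrow(group_a)),
      group_b = sprintf("%.1f%%", 100 * xb / nrow(group_b)),
      p_value = ct$p_value)
  }
  out <- do.call(rbind, rows)
  out$p_rounded <- round(out$p_value, 2)
  rownames(out) <- NULL
  out
}
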