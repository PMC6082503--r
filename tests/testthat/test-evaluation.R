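test_that("classification is negative strictly below the threshold, positive otherwise", {
  expect_equal(classify_scores(c(1, 2, 3), 2), c(0L, 1L, 1L))
  expect_equal(classify_scores(c(1, 2, 3), 0), c(1L, 1L, 1L))
  expect_equal(classify_scores(c(1, 2, 3), 4), c(0L, 0L, 0L))
  expect_error(classify_scores(c(1, NA), 1), "finite")
})

test_that("diagnostic metrics follow the standard formulas", {
  # 23 true positives, 2 false negatives, 43 true negatives, 7 false pos
  pred <- c(rep(1, 23), rep(0, 2), rep(0, 43), rep(1, 7))
  lab <- c(rep(1, 25), rep(0, 50))
  cm <- confusion_metrics(pred, lab)
  expect_equal(c(cm$tp, cm$fn, cm$tn, cm$fp), c(23, 2, 43, 7))
  expect_equal(cm$n, 75)
  expect_equal(cm$sensitivity, 23 / 25)   # 0.92
  expect_equal(cm$specificity, 43 / 50)
  expect_equal(cm$npv, 43 / 45)
  expect_equal(cm$ppv, 23 / 30)
})

test_that("zero-denominator metrics are absent, not zero, and raise no error", {
  cm <- confusion_metrics(c(0, 1, 0), c(0, 0, 0))   # no positives
  expect_true(is.na(cm$sensitivity))
  expect_equal(cm$specificity, 2 / 3)
  cm2 <- confusion_metrics(c(1, 1), c(0, 1))        # nothing predicted neg
  expect_true(is.na(cm2$npv))
})

test_that("threshold selection maximises specificity above the sensitivity floor", {
  th <- select_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1),
                         sens_floor = 0.9)
  expect_gt(as.numeric(th), 0.2)
  expect_lte(as.numeric(th), 0.8)
  expect_equal(attr(th, "sensitivity"), 1)
  expect_equal(attr(th, "specificity"), 1)
  expect_true(attr(th, "floor_met"))

  # unreachable floor: fall back to maximal sensitivity with a warning
  expect_warning(
    th2 <- select_threshold(c(3, 1, 2), c(1, 0, 0), sens_floor = 2),
    "maximal-sensitivity")
  expect_equal(attr(th2, "sensitivity"), 1)
  expect_false(attr(th2, "floor_met"))

  # floor 0: the sensitivity tie-break rejects the all-negative rule
  th3 <- select_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1),
                          sens_floor = 0)
  expect_equal(attr(th3, "sensitivity"), 1)
  expect_equal(attr(th3, "specificity"), 1)
})

test_that("threshold selection on overlapping scores picks a defensible operating point", {
  set.seed(14)
  sc <- c(rnorm(40, 0), rnorm(20, 1.2))
  lb <- c(rep(0, 40), rep(1, 20))
  th <- select_threshold(sc, lb, sens_floor = 0.9)
  cm <- confusion_metrics(classify_scores(sc, as.numeric(th)), lb)
  expect_gte(cm$sensitivity, 0.9)
  # no other operating point with sens >= 0.9 has higher specificity
  for (t in sort(unique(sc))) {
    cmt <- confusion_metrics(classify_scores(sc, t), lb)
    if (!is.na(cmt$sensitivity) && cmt$sensitivity >= 0.9)
      expect_lte(cmt$specificity, cm$specificity)
  }
})

sens_fn <- function(p, l) confusion_metrics(p, l)$sensitivity

test_that("a zero-variance statistic collapses the bootstrap interval onto the point", {
  pred <- rep(1, 30); lab <- rep(1, 30)   # everything correct
  ci <- bootstrap_ci(sens_fn, pred, lab, n_boot = 200, seed = 1)
  expect_equal(as.numeric(ci), c(1, 1))
})

test_that("bootstrap intervals are deterministic per seed and bracket the estimate", {
  set.seed(24)
  lab <- rep(c(1, 0), c(25, 50))
  pred <- ifelse(lab == 1, rbinom(75, 1, 0.9), rbinom(75, 1, 0.3))
  ci1 <- bootstrap_ci(sens_fn, pred, lab, n_boot = 500, seed = 42)
  ci2 <- bootstrap_ci(sens_fn, pred, lab, n_boot = 500, seed = 42)
  expect_identical(ci1, ci2)
  point <- attr(ci1, "point")
  expect_lte(ci1[1], point)
  expect_gte(ci1[2], point)
  expect_gte(ci1[1], 0)
  expect_lte(ci1[2], 1)
})

test_that("BCa endpoints agree with the boot package on a tie-free statistic", {
  skip_if_not_installed("boot")
  set.seed(34)
  x <- rexp(60)                       # skewed, continuous: no ties
  lab <- rep(0:1, 30)
  mean_fn <- function(v, l) mean(v)
  ci <- bootstrap_ci(mean_fn, x, lab, n_boot = 4000, seed = 7)
  set.seed(7)
  b <- boot::boot(x, function(d, i) mean(d[i]), R = 4000)
  ref <- boot::boot.ci(b, type = "bca")$bca[4:5]
  expect_equal(as.numeric(ci), ref, tolerance = 0.02)
})

test_that("mostly-degenerate resamples raise an informative error", {
  lab <- c(1, 1, 0)
  pred <- c(1, 1, 0)
  # defined on the full sample, undefined on ~56% of resamples
  needs_both <- function(p, l) {
    if (sum(l == 1) < 2 || sum(l == 0) < 1) NA_real_ else mean(p)
  }
  expect_error(
    bootstrap_ci(needs_both, pred, lab, n_boot = 400, seed = 3),
    "larger cohort")
})

test_that("the pooled t-test reproduces a printed summary-statistics comparison", {
  r <- ttest_summary(61.5, 10.7, 512, 59.0, 9.8, 94)
  expect_equal(round(r$p_value, 2), 0.04)
  expect_equal(r$df, 604)
  # identical groups: t = 0, p = 1
  expect_equal(ttest_summary(5, 1, 30, 5, 1, 30)$p_value, 1)
  # overwhelming separation: analytic tail bound
  expect_lt(ttest_summary(1, 1, 1000, 0, 1, 1000)$p_value, 1e-10)
})

test_that("the chi-square comparison matches the base test and handles identity", {
  r <- chisq_counts(308, 512, 65, 94)
  ref <- suppressWarnings(
    stats::chisq.test(rbind(c(308, 204), c(65, 29)), correct = FALSE))
  expect_equal(r$p_value, unname(ref$p.value))
  expect_equal(chisq_counts(30, 60, 15, 30)$p_value, 1)
})

test_that("the demographics table compares cohorts variable by variable", {
  co <- simulate_cohort(small_config(seed = 6))
  s <- co$subjects
  dev <- s[s$split != "verification", ]
  ver <- s[s$split == "verification", ]
  tab <- demographic_table(dev, ver)
  expect_setequal(tab$variable,
                  c("age", "bmi", "heart_rate", "male", "cad_positive"))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  expect_equal(tab$p_rounded, round(tab$p_value, 2))
  # a cohort compared with itself shows no differences
  same <- demographic_table(dev, dev)
  expect_true(all(abs(same$p_value - 1) < 1e-12))
})
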