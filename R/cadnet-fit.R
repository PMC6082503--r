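# Assemble the per-split data lists consumed by evaluate_genome()
.split_data <- function(cohort, split) {
  idx <- which(cohort$subjects$split == split)
  if (length(idx) == 0) stop("cohort has no '", split, "' split")
  list(x = cohort$features[idx, , drop = FALSE],
       gensini = cohort$subjects$gensini_modified[idx],
       label = cohort$subjects$cad_label[idx],
       noise = cohort$subjects$noise_volume[idx],
       subject_id = cohort$subjects$subject_id[idx])
}

.feature_hash <- function(feature_names) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(feature_names, tmp)
  unname(tools::md5sum(tmp))
}

#' Develop the GA-tuned elastic-net CAD classifier
#'
#' The main fitting function. On the training and validation splits of a
#' cohort it (1) sets the four noise-volume thresholds at the 60/70/80/90th
#' percentiles of the training noise volumes and builds the five nested
#' noise subsets per split, (2) evolves the five hyperparameters (elastic
#' net `alpha` and `lambda`, upweight factor, Gensini weighting threshold,
#' correlation reduction threshold) with a genetic algorithm whose fitness
#' is the noise-subset-weighted sum of squared AUC shortfalls, (3) refits
#' the best genome on the training split, and (4) freezes the clinical
#' decision threshold on the validation ROC curve (maximal specificity
#' subject to sensitivity >= `sens_floor`). Verification rows are never
#' touched; the returned object records which splits were accessed.
#'
#' @param cohort A `cad_cohort` with train/validation splits (a
#'   verification split may be present but is ignored here).
#' @param ga A [ga_config()].
#' @param sens_floor Minimum validation sensitivity for threshold selection.
#' @param noise_quantiles Training-noise quantiles defining the four subset
#'   thresholds.
#' @param enet_tol,enet_max_sweeps Elastic-net convergence controls for the
#'   GA inner loop (rank-based fitness is insensitive to tighter
#'   tolerances).
#' @param refit_tol,refit_max_sweeps Tighter convergence controls for the
#'   single final refit of the best genome.
#' @param seed Optional master seed; set once, it makes the whole
#'   development run (GA included) deterministic.
#' @param verbose Print per-generation progress.
#' @return An object of class `cadnet`: the tuned `genome`, the frozen
#'   `reduction`, elastic-net `fit`, decision `threshold` (with attributes),
#'   GA history (`ga`), the noise `partition` thresholds, validation-split
#'   diagnostics, and the feature hash used for integrity checks.
#' @seealso [cadnet_verify()] for the blinded verification report,
#'   [predict.cadnet()], [plot.cadnet()].
#' @export
cadnet <- function(cohort, ga = ga_config(), sens_floor = 0.90,
                   noise_quantiles = c(0.6, 0.7, 0.8, 0.9),
                   enet_tol = 1e-4, enet_max_sweeps = 1500L,
                   refit_tol = 1e-5, refit_max_sweeps = 20000L,
                   seed = NULL, verbose = FALSE) {
  stopifnot(inherits(cohort, "cad_cohort"))
  if (!is.null(seed)) set.seed(seed)
  train <- .split_data(cohort, "train")
  val <- .split_data(cohort, "validation")

  thresholds <- unname(quantile(train$noise, noise_quantiles, type = 7))
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("noise thresholds are not strictly ascending; ",
         "noise volumes may be degenerate")
  partition <- build_noise_subsets(train$noise, val$noise, thresholds)

  res <- ga_evolve(train, val, partition, config = ga,
                   enet_tol = enet_tol, enet_max_sweeps = enet_max_sweeps)
  if (verbose) print(res)

  # single tight refit of the winning genome; if it cannot reach the
  # tighter tolerance within the sweep budget, fall back to the search
  # settings under which the genome was scored
  final <- tryCatch(
    evaluate_genome(res$best_genome, train, val, partition,
                    enet_tol = refit_tol,
                    enet_max_sweeps = refit_max_sweeps),
    cadnet_nonconvergence = function(e) {
      warning("final refit did not reach refit_tol; ",
              "using the search-stage tolerance instead")
      evaluate_genome(res$best_genome, train, val, partition,
                      enet_tol = enet_tol,
                      enet_max_sweeps = enet_max_sweeps)
    })
  if (!is.finite(final$fitness))
    stop("the best genome does not yield a finite fitness")

  threshold <- select_threshold(final$scores$val, val$label, sens_floor)

  structure(list(
    genome = res$best_genome,
    reduction = final$reduction,
    fit = final$fit,
    threshold = threshold,
    sens_floor = sens_floor,
    ga = res,
    partition_thresholds = thresholds,
    noise_quantiles = noise_quantiles,
    fitness = final$fitness,
    auc_train = final$auc_train,
    auc_val = final$auc_val,
    validation = list(scores = final$scores$val, labels = val$label,
                      auc = final$auc_val[1]),
    feature_names = colnames(cohort$features),
    feature_hash = .feature_hash(colnames(cohort$features)),
    n_train = length(train$label), n_val = length(val$label),
    splits_accessed = c("train", "validation"),
    call = match.call()),
    class = "cadnet")
}

#' @export
print.cadnet <- function(x, ...) {
  cat("GA-tuned elastic net CAD classifier\n")
  cat(sprintf("  trained on %d subjects, threshold frozen on %d validation subjects\n",
              x$n_train, x$n_val))
  g <- x$genome
  cat(sprintf("  genome: alpha %.3f, lambda %.4g, upweight %.2f, Gensini threshold %.3f, corr threshold %.3f\n",
              g[["alpha"]], 10^g[["log_lambda"]], g[["upweight_factor"]],
              g[["gensini_weight_threshold"]], g[["corr_threshold"]]))
  cat(sprintf("  features: %d of %d kept after correlation reduction, %d nonzero weights\n",
              length(x$reduction$kept_indices), x$reduction$n_features,
              sum(x$fit$coefficients != 0)))
  cat(sprintf("  decision threshold %.4f (validation sensitivity %.2f, specificity %.2f)\n",
              as.numeric(x$threshold), attr(x$threshold, "sensitivity"),
              attr(x$threshold, "specificity")))
  cat(sprintf("  GA: %d generations, fitness %.5f; validation AUC %.3f\n",
              x$ga$generations, x$fitness, x$validation$auc))
  invisible(x)
}

#' @export
summary.cadnet <- function(object, ...) {
  structure(list(model = object), class = "summary.cadnet")
}

#' @export
print.summary.cadnet <- function(x, ...) {
  m <- x$model
  print(m)
  cat("\nPer-subset AUCs (nested noise subsets 1..5):\n")
  print(round(rbind(train = m$auc_train, validation = m$auc_val), 4))
  w <- m$fit$coefficients
  nz <- w[w != 0]
  nz <- nz[order(-abs(nz))]
  cat(sprintf("\nTop coefficients (of %d nonzero):\n", length(nz)))
  print(round(head(nz, 10), 5))
  invisible(x)
}

#' @export
coef.cadnet <- function(object, ...) coef(object$fit)

#' Predict CAD scores or classes from a developed model
#'
#' @param object A `cadnet` model (fitted or read back from JSON).
#' @param newdata A `cad_cohort`, or a feature matrix with the model's full
#'   original columns.
#' @param type `"score"` for the continuous modified-Gensini prediction,
#'   `"class"` for the 0/1 decision at the frozen threshold.
#' @param split For a `cad_cohort`, restrict to one split
#'   (e.g. `"verification"`); default uses all rows.
#' @param ... Unused.
#' @return Named numeric (scores) or integer (classes) vector.
#' @export
predict.cadnet <- function(object, newdata, type = c("score", "class"),
                           split = NULL, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "cad_cohort")) {
    x <- newdata$features
    if (!is.null(split)) x <- x[newdata$subjects$split == split, ,
                                drop = FALSE]
  } else x <- as.matrix(newdata)
  if (!identical(colnames(x), object$feature_names))
    stop("newdata columns do not match the model's training features")
  scores <- predict(object$fit,
                    x[, object$reduction$kept_indices, drop = FALSE])
  names(scores) <- rownames(x)
  if (type == "score") scores
  else setNames(classify_scores(scores, as.numeric(object$threshold)),
                rownames(x))
}

#' Plot GA convergence and the validation ROC curve
#'
#' @param x A `cadnet` model.
#' @param which 1 = best/mean fitness by generation, 2 = validation ROC with
#'   the frozen operating point.
#' @param ... Passed to the base plot calls.
#' @export
plot.cadnet <- function(x, which = 1:2, ...) {
  op <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(op))
  if (1 %in% which) {
    h <- x$ga$history
    graphics::plot(h$generation, h$best_ever, type = "s", lwd = 2,
                   xlab = "generation", ylab = "fitness",
                   main = "GA convergence", ...)
    graphics::lines(h$generation, h$mean_fitness, lty = 2, col = "grey40")
    graphics::legend("bottomright", c("best ever", "population mean"),
                     lty = c(1, 2), lwd = c(2, 1),
                     col = c("black", "grey40"), bty = "n")
  }
  if (2 %in% which) {
    sc <- x$validation$scores; lb <- x$validation$labels
    cand <- c(-Inf, sort(unique(sc)), Inf)
    pts <- vapply(cand, function(t) {
      cm <- confusion_metrics(as.integer(sc >= t), lb)
      c(fpr = 1 - cm$specificity, tpr = cm$sensitivity)
    }, numeric(2))
    graphics::plot(pts["fpr", ], pts["tpr", ], type = "l", lwd = 2,
                   xlab = "1 - specificity", ylab = "sensitivity",
                   main = sprintf("Validation ROC (AUC %.3f)",
                                  x$validation$auc), ...)
    graphics::abline(0, 1, lty = 3, col = "grey60")
    graphics::points(1 - attr(x$threshold, "specificity"),
                     attr(x$threshold, "sensitivity"),
                     pch = 19, col = "red")
  }
  invisible(x)
}

#' Blinded verification of a frozen model
#'
#' Applies the frozen predictor once to the verification split: continuous
#' scores, classification at the frozen threshold, the confusion matrix,
#' and sensitivity/specificity/NPV/PPV/AUC with BCa bootstrap confidence
#' intervals.
#'
#' @param object A `cadnet` model.
#' @param cohort A `cad_cohort` containing a verification split.
#' @param n_boot Bootstrap resamples per metric.
#' @param level Confidence level.
#' @param seed Optional seed for the bootstrap (identical seed, identical
#'   intervals).
#' @return An object of class `cadnet_report`: `confusion`, a `metrics`
#'   data frame (estimate, ci_low, ci_high per metric), `n`, `n_boot`,
#'   `seed`.
#' @export
cadnet_verify <- function(object, cohort, n_boot = 2000L, level = 0.95,
                          seed = NULL) {
  stopifnot(inherits(object, "cadnet"), inherits(cohort, "cad_cohort"))
  if (!identical(object$feature_hash,
                 .feature_hash(colnames(cohort$features))))
    stop("model feature hash does not match this cohort's feature matrix; ",
         "refusing to verify against mismatched features")
  ver <- .split_data(cohort, "verification")
  scores <- predict(object$fit,
                    ver$x[, object$reduction$kept_indices, drop = FALSE])
  preds <- classify_scores(scores, as.numeric(object$threshold))
  cm <- confusion_metrics(preds, ver$label)

  if (!is.null(seed)) set.seed(seed)
  metric_fns <- list(
    sensitivity = function(p, l) confusion_metrics(p, l)$sensitivity,
    specificity = function(p, l) confusion_metrics(p, l)$specificity,
    npv = function(p, l) confusion_metrics(p, l)$npv,
    ppv = function(p, l) confusion_metrics(p, l)$ppv)
  rows <- lapply(names(metric_fns), function(m) {
    est <- metric_fns[[m]](preds, ver$label)
    if (is.na(est))
      return(data.frame(metric = m, estimate = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_))
    ci <- bootstrap_ci(metric_fns[[m]], preds, ver$label,
                       n_boot = n_boot, level = level)
    data.frame(metric = m, estimate = est, ci_low = ci[1], ci_high = ci[2])
  })
  auc_ci <- bootstrap_ci(function(s, l) rank_auc(s, l), scores, ver$label,
                         n_boot = n_boot, level = level)
  rows[[length(rows) + 1]] <-
    data.frame(metric = "auc", estimate = attr(auc_ci, "point"),
               ci_low = auc_ci[1], ci_high = auc_ci[2])

  structure(list(confusion = cm,
                 metrics = do.call(rbind, rows),
                 scores = scores, labels = ver$label,
                 threshold = as.numeric(object$threshold),
                 n = cm$n, n_boot = n_boot, level = level, seed = seed),
            class = "cadnet_report")
}

#' @export
print.cadnet_report <- function(x, ...) {
  cat(sprintf("Blinded verification report (n = %d)\n", x$n))
  cat(sprintf("  TP %d, FP %d, TN %d, FN %d at threshold %.4f\n",
              x$confusion$tp, x$confusion$fp, x$confusion$tn,
              x$confusion$fn, x$threshold))
  lv <- round(100 * x$level)
  for (i in seq_len(nrow(x$metrics))) {
    r <- x$metrics[i, ]
    if (is.na(r$estimate)) {
      cat(sprintf("  %-12s undefined on this cohort\n", r$metric))
    } else if (r$metric == "auc") {
      cat(sprintf("  %-12s %.2f (%d%% CI: %.2f-%.2f)\n", "AUC",
                  r$estimate, lv, r$ci_low, r$ci_high))
    } else {
      cat(sprintf("  %-12s %.0f%% (%d%% CI: %.0f%%-%.0f%%)\n", r$metric,
                  100 * r$estimate, lv, 100 * r$ci_low, 100 * r$ci_high))
    }
  }
  invisible(x)
}

#' Text rendering of a verification report
#'
#' @param report A `cadnet_report`.
#' @return Character vector of report lines.
#' @export
format_report <- function(report) {
  utils::capture.output(print(report))
}
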