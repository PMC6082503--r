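#' Serialise a developed model to JSON
#'
#' Writes everything needed to reproduce predictions bit-exactly: the tuned
#' genome, the kept feature indices, coefficients/intercept at full
#' precision, the elastic-net settings, the frozen threshold and the
#' feature hash. No timestamps are included, so the file is byte-identical
#' across reruns with the same seed.
#'
#' @param model A `cadnet` model.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  obj <- list(
    genome = as.list(model$genome),
    kept_indices = model$reduction$kept_indices,
    reduction_threshold = model$reduction$threshold,
    n_features = model$reduction$n_features,
    coefficients = unname(model$fit$coefficients),
    coefficient_names = names(model$fit$coefficients),
    intercept = model$fit$intercept,
    alpha = model$fit$alpha,
    lambda = model$fit$lambda,
    center = unname(model$fit$center),
    scale = unname(model$fit$scale),
    threshold = as.numeric(model$threshold),
    threshold_sensitivity = attr(model$threshold, "sensitivity"),
    threshold_specificity = attr(model$threshold, "specificity"),
    sens_floor = model$sens_floor,
    partition_thresholds = model$partition_thresholds,
    feature_names = model$feature_names,
    feature_hash = model$feature_hash,
    fitness = model$fitness,
    auc_train = model$auc_train,
    auc_val = model$auc_val,
    ga_generations = model$ga$generations,
    ga_truncated = model$ga$truncated)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a model written by [write_model()]
#'
#' @param path Model JSON file.
#' @return A `cadnet` object sufficient for [predict.cadnet()] and
#'   [cadnet_verify()].
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- setNames(as.numeric(obj$coefficients), obj$coefficient_names)
  fit <- structure(list(coefficients = w, intercept = obj$intercept,
                        alpha = obj$alpha, lambda = obj$lambda,
                        center = as.numeric(obj$center),
                        scale = as.numeric(obj$scale),
                        standardize = TRUE),
                   class = "enet")
  threshold <- structure(obj$threshold,
                         sensitivity = obj$threshold_sensitivity,
                         specificity = obj$threshold_specificity,
                         floor_met = TRUE)
  structure(list(
    genome = unlist(obj$genome),
    reduction = structure(list(kept_indices = as.integer(obj$kept_indices),
                               dropped_pairs = data.frame(
                                 dropped = integer(), retained = integer(),
                                 abs_r = numeric()),
                               zero_variance = integer(0),
                               threshold = obj$reduction_threshold,
                               n_features = obj$n_features),
                          class = "reduction_result"),
    fit = fit,
    threshold = threshold,
    sens_floor = obj$sens_floor,
    partition_thresholds = as.numeric(obj$partition_thresholds),
    fitness = obj$fitness,
    auc_train = as.numeric(obj$auc_train),
    auc_val = as.numeric(obj$auc_val),
    feature_names = obj$feature_names,
    feature_hash = obj$feature_hash),
    class = "cadnet")
}

#' Generate and write a synthetic cohort with a manifest
#'
#' Writes the three cohort CSVs plus `manifest.json` recording the
#' configuration, the seed and the MD5 hash of every file, so a rerun with
#' the same configuration reproduces the files hash-identically.
#'
#' @param dir Output directory.
#' @param config A [cohort_config()].
#' @param gensini A [gensini_config()].
#' @param seed Optional override of `config$seed`.
#' @return Invisibly, the generated `cad_cohort`.
#' @export
pipeline_generate <- function(dir, config = cohort_config(),
                              gensini = gensini_config(), seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  cohort <- simulate_cohort(config, gensini)
  paths <- write_cohort(cohort, dir)
  manifest <- list(
    config = unclass(config),
    seed = config$seed,
    n_subjects = nrow(cohort$subjects),
    prevalence = mean(cohort$subjects$cad_label),
    files = as.list(setNames(unname(tools::md5sum(paths)),
                             basename(paths))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(cohort)
}

#' Develop a model from cohort files on disk
#'
#' Reads the cohort, runs the full development stage ([cadnet()]: Gensini
#' targets are already in the cohort file, noise-subset construction, GA
#' evolution, final refit, validation threshold selection) and writes
#' `model.json` plus the per-generation GA log `ga_log.csv`. Verification
#' rows are never read by the development stage.
#'
#' @param dir Directory with the cohort files; outputs are written here too.
#' @param ga A [ga_config()].
#' @param sens_floor Passed to [cadnet()].
#' @param seed Master development seed.
#' @param ... Further arguments to [cadnet()].
#' @return Invisibly, the `cadnet` model.
#' @export
pipeline_develop <- function(dir, ga = ga_config(), sens_floor = 0.90,
                             seed = 1L, ...) {
  cohort <- read_cohort(dir)
  model <- cadnet(cohort, ga = ga, sens_floor = sens_floor, seed = seed,
                  ...)
  write_model(model, file.path(dir, "model.json"))
  utils::write.csv(model$ga$history, file.path(dir, "ga_log.csv"),
                   row.names = FALSE)
  invisible(model)
}

#' Blindly verify a frozen model against cohort files on disk
#'
#' Refuses to run when the model's feature hash does not match the cohort's
#' feature matrix. Writes `report.json` and a human-readable `report.txt`
#' in the paper's "metric (95% CI: lo-hi)" format.
#'
#' @param dir Directory with the cohort files.
#' @param model A `cadnet` model, or `NULL` to read `model.json` from
#'   `dir`.
#' @param n_boot,level,seed Passed to [cadnet_verify()].
#' @return Invisibly, the `cadnet_report`.
#' @export
pipeline_verify <- function(dir, model = NULL, n_boot = 2000L,
                            level = 0.95, seed = 1L) {
  cohort <- read_cohort(dir)
  if (is.null(model)) model <- read_model(file.path(dir, "model.json"))
  report <- cadnet_verify(model, cohort, n_boot = n_boot, level = level,
                          seed = seed)
  jsonlite::write_json(
    list(n = report$n,
         confusion = report$confusion[c("tp", "fp", "tn", "fn")],
         threshold = report$threshold,
         metrics = report$metrics,
         n_boot = n_boot, level = level, seed = seed),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  writeLines(format_report(report), file.path(dir, "report.txt"))
  invisible(report)
}

#' Demographics comparison of the development and verification cohorts
#'
#' @param dir Directory with the cohort files.
#' @return The [demographic_table()] comparing development
#'   (train + validation) against verification subjects; also written to
#'   `demographics.csv`.
#' @export
pipeline_demographics <- function(dir) {
  cohort <- read_cohort(dir)
  s <- cohort$subjects
  dev <- s[s$split %in% c("train", "validation"), ]
  ver <- s[s$split == "verification", ]
  tab <- demographic_table(dev, ver)
  utils::write.csv(tab, file.path(dir, "demographics.csv"),
                   row.names = FALSE)
  tab
}

#' Run the full generate / develop / verify pipeline
#'
#' Convenience wrapper reproducing the study's two-stage design end to end
#' with one master seed: the cohort seed, GA seed and bootstrap seed are
#' derived deterministically from it.
#'
#' @param dir Working directory for all artifacts.
#' @param config A [cohort_config()].
#' @param ga A [ga_config()].
#' @param sens_floor,n_boot As elsewhere.
#' @param seed Master seed.
#' @return List with elements `cohort`, `model`, `report`, `demographics`.
#' @export
run_pipeline <- function(dir, config = cohort_config(), ga = ga_config(),
                         sens_floor = 0.90, n_boot = 2000L, seed = 1L) {
  seed <- as.integer(seed)
  cohort <- pipeline_generate(dir, config, seed = seed)
  model <- pipeline_develop(dir, ga = ga, sens_floor = sens_floor,
                            seed = seed + 1L)
  report <- pipeline_verify(dir, model = model, n_boot = n_boot,
                            seed = seed + 2L)
  demographics <- pipeline_demographics(dir)
  list(cohort = cohort, model = model, report = report,
       demographics = demographics)
}
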