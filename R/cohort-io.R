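# Full-precision CSV writing: doubles are formatted with 17 significant
# digits so that read(write(x)) round-trips bit-exactly.
.write_csv_precise <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]]))
      out[[j]] <- ifelse(is.na(out[[j]]), NA,
                         sprintf("%.17g", out[[j]]))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "NA")
}

.require_columns <- function(df, cols, file) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing required column(s): %s", file,
                 paste(miss, collapse = ", ")))
}

#' Write a cohort to three CSV files
#'
#' `cohort.csv` holds one row per subject (id, split, demographics, noise
#' volume, collaterals flag, lesion count, CAD label, modified Gensini
#' score); `lesions.csv` the per-lesion list keyed by `subject_id`;
#' `features.csv` the feature matrix (`subject_id`, `f001`...,
#' `age`, `sex_code`, `heart_rate`). All numeric fields are written at full
#' precision so the round trip is exact.
#'
#' @param cohort A `cad_cohort` from [simulate_cohort()] or [read_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("cohort.csv", "lesions.csv", "features.csv"))
  subj <- cohort$subjects[, c("subject_id", "split", "age", "sex",
                              "heart_rate", "bmi", "noise_volume",
                              "collaterals", "n_lesions", "cad_label",
                              "gensini_modified")]
  .write_csv_precise(subj, paths[1])
  .write_csv_precise(cohort$lesions, paths[2])
  feat <- data.frame(subject_id = rownames(cohort$features),
                     cohort$features, check.names = FALSE,
                     stringsAsFactors = FALSE)
  .write_csv_precise(feat, paths[3])
  invisible(paths)
}

#' Read a cohort written by [write_cohort()]
#'
#' Validates the schema of all three files: a missing required column is an
#' error naming the file and column, never a silent default.
#'
#' @param dir Directory containing `cohort.csv`, `lesions.csv` and
#'   `features.csv`.
#' @return A `cad_cohort` (the `config` element is `NULL`; it lives in the
#'   pipeline manifest).
#' @export
read_cohort <- function(dir) {
  paths <- file.path(dir, c("cohort.csv", "lesions.csv", "features.csv"))
  for (p in paths) if (!file.exists(p)) stop("missing file: ", p)

  subj <- utils::read.csv(paths[1], stringsAsFactors = FALSE)
  .require_columns(subj, c("subject_id", "split", "age", "sex",
                           "heart_rate", "bmi", "noise_volume",
                           "collaterals", "n_lesions", "cad_label",
                           "gensini_modified"), "cohort.csv")
  subj$collaterals <- as.logical(subj$collaterals)
  subj$n_lesions <- as.integer(subj$n_lesions)
  subj$cad_label <- as.integer(subj$cad_label)

  les <- utils::read.csv(paths[2], stringsAsFactors = FALSE,
                         colClasses = c(subject_id = "character"))
  .require_columns(les, c("subject_id", "stenosis", "segment",
                          "ffr_measured", "ffr"), "lesions.csv")
  les$ffr_measured <- as.logical(les$ffr_measured)
  les$stenosis <- as.numeric(les$stenosis)
  les$ffr <- as.numeric(les$ffr)
  les$segment <- as.character(les$segment)

  feat <- utils::read.csv(paths[3], stringsAsFactors = FALSE,
                          check.names = FALSE)
  .require_columns(feat, c("subject_id", "age", "sex_code", "heart_rate"),
                   "features.csv")
  if (!identical(feat$subject_id, subj$subject_id))
    stop("features.csv subject_id column does not match cohort.csv")
  features <- as.matrix(feat[, setdiff(names(feat), "subject_id"),
                             drop = FALSE])
  if (!is.numeric(features))
    stop("features.csv contains non-numeric feature values")
  rownames(features) <- feat$subject_id

  structure(list(subjects = subj, lesions = les, features = features,
                 config = NULL),
            class = "cad_cohort")
}
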