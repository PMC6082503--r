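#' Correlation-based feature reduction
#'
#' Greedy forward scan in ascending column order: a feature is dropped when
#' its absolute Pearson correlation with an already-retained feature of
#' smaller index exceeds `threshold`; otherwise it is retained. The scan is
#' deterministic, so the smaller-index member of any correlated pair always
#' survives. Correlations must be computed on training rows only so the
#' verification split stays blind.
#'
#' Zero-variance features have undefined correlation; they are never dropped
#' for correlation and are flagged in the result.
#'
#' @param x Feature matrix (training rows by features), >= 2 rows.
#' @param threshold Correlation threshold in (0, 1\]. The reference pipeline
#'   uses 0.907.
#' @param cor_matrix Optional precomputed `abs(cor(x))`, to avoid
#'   recomputation when scanning many thresholds over the same matrix.
#' @return An object of class `reduction_result`: `kept_indices` (ascending),
#'   `dropped_pairs` (data frame with `dropped`, `retained`, `abs_r`),
#'   `zero_variance` (flagged column indices), `threshold`, `n_features`.
#' @examples
#' x <- matrix(rnorm(200), 50, 4)
#' x[, 4] <- x[, 1]                      # exact duplicate
#' reduce_by_correlation(x, 0.907)$kept_indices   # 1 2 3
#' @export
reduce_by_correlation <- function(x, threshold, cor_matrix = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("at least 2 subjects are required")
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  if (is.null(cor_matrix))
    cor_matrix <- abs(suppressWarnings(stats::cor(x)))
  p <- ncol(x)
  sds <- apply(x, 2, stats::sd)
  zero <- !is.finite(sds) | sds == 0
  kept <- logical(p)
  drp <- integer(0); ret <- integer(0); rr <- numeric(0)
  for (j in seq_len(p)) {
    if (zero[j]) { kept[j] <- TRUE; next }
    ks <- which(kept & !zero)
    if (length(ks)) {
      r <- cor_matrix[ks, j]
      over <- which(r > threshold)
      if (length(over)) {
        best <- over[which.max(r[over])]
        drp <- c(drp, j); ret <- c(ret, ks[best]); rr <- c(rr, r[best])
        next
      }
    }
    kept[j] <- TRUE
  }
  structure(list(
    kept_indices = which(kept),
    dropped_pairs = data.frame(dropped = drp, retained = ret, abs_r = rr),
    zero_variance = which(zero),
    threshold = threshold,
    n_features = p), class = "reduction_result")
}

#' @export
print.reduction_result <- function(x, ...) {
  cat(sprintf(
    "Correlation reduction at |r| > %.4g: %d of %d features kept (%d dropped)\n",
    x$threshold, length(x$kept_indices), x$n_features, nrow(x$dropped_pairs)))
  if (length(x$zero_variance))
    cat("  zero-variance features flagged:",
        paste(x$zero_variance, collapse = ", "), "\n")
  invisible(x)
}
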