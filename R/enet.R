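#' Fit a weighted elastic net by cyclic coordinate descent
#'
#' Minimises the unnormalised penalised least-squares loss
#' \deqn{\sum_i u_i (y_i - x_i'W - b)^2 +
#'       \lambda\,(0.5\,(1-\alpha)\|W\|_2^2 + \alpha\|W\|_1)}
#' with an unpenalised intercept \eqn{b}. Note the absence of any
#' \eqn{1/(2n)} normalisation: \eqn{\lambda} scales against the raw weighted
#' residual sum of squares. \eqn{\alpha = 1} is the lasso, \eqn{\alpha = 0}
#' ridge regression with the stationarity condition
#' \eqn{(X'X + 0.5\lambda I)W = X'y} on centred data.
#'
#' Coordinates are updated cyclically in ascending column order by
#' soft-thresholding; the fit has converged when the largest per-sweep
#' coefficient change (on the working, i.e. standardized, scale) drops below
#' `tol`. The intercept is handled exactly by weighted centring of `x` and
#' `y` before the descent.
#'
#' @param x Numeric design matrix (subjects by features), no missing values.
#' @param y Numeric response (the modified Gensini score in the CAD
#'   pipeline).
#' @param weights Nonnegative per-subject weights `u`; default all 1. See
#'   [apply_upweighting()].
#' @param alpha Mixing fraction in \[0, 1\] between the L1 and L2 penalties.
#' @param lambda Penalty strength, >= 0.
#' @param standardize Standardise columns to zero (weighted) mean and unit
#'   (weighted) variance before fitting; coefficients are returned on the
#'   original scale. Zero-variance columns are pinned to coefficient 0 with
#'   a warning.
#' @param tol Convergence tolerance on the max coefficient change per sweep.
#' @param max_sweeps Sweep budget; exceeding it raises an error of class
#'   `cadnet_nonconvergence` carrying the last objective value.
#' @param track_objective Record the penalised objective after every sweep
#'   (in `objective_path`); used to verify its monotone decrease.
#' @return An object of class `enet` with elements `coefficients` (original
#'   scale), `intercept`, `alpha`, `lambda`, `center`, `scale`, `sweeps`,
#'   `objective`, `objective_path`, `fitted.values`, `residuals`.
#' @examples
#' x <- cbind(a = c(1, 2, 3))
#' fit <- enet_fit(x, c(2, 4, 6), alpha = 1, lambda = 0,
#'                 standardize = FALSE)
#' coef(fit)          # intercept 0, slope 2
#' @export
enet_fit <- function(x, y, weights = NULL, alpha = 0.5, lambda = 0,
                     standardize = TRUE, tol = 1e-8, max_sweeps = 10000L,
                     track_objective = FALSE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x); p <- ncol(x)
  if (n < 2) stop("at least 2 subjects are required")
  if (length(y) != n) stop("x and y row counts differ")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("weights length must equal nrow(x)")
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(!is.finite(weights)))
    stop("x, y and weights must be finite with no missing values")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (lambda < 0) stop("lambda must be nonnegative")
  if (tol <= 0) stop("tol must be positive")

  su <- sum(weights)
  xm <- colSums(x * weights) / su
  ym <- sum(y * weights) / su
  xc <- sweep(x, 2, xm, "-")
  yc <- y - ym
  if (standardize) {
    sc <- sqrt(colSums(weights * xc^2) / su)
    zero <- sc < .Machine$double.eps^0.5
    if (any(zero)) {
      warning(sum(zero), " zero-variance feature(s); coefficient pinned to 0")
      sc[zero] <- 1
      xc[, zero] <- 0
    }
    xs <- sweep(xc, 2, sc, "/")
  } else {
    sc <- rep(1, p)
    xs <- xc
  }

  res <- enet_cd(xs, yc, weights, alpha, lambda, tol,
                 as.integer(max_sweeps), track_objective)
  if (!res$converged)
    stop(errorCondition(
      sprintf(paste0("elastic net did not converge in %d sweeps ",
                     "(last objective %.6g); increase max_sweeps or tol"),
              max_sweeps, res$objective),
      objective = res$objective,
      class = c("cadnet_nonconvergence", "error", "condition")))

  w <- res$w / sc
  b <- ym - sum(xm * w)
  names(w) <- colnames(x)
  fitted <- drop(x %*% w) + b
  structure(list(coefficients = w, intercept = b, alpha = alpha,
                 lambda = lambda, standardize = standardize,
                 center = xm, scale = sc, sweeps = res$sweeps,
                 objective = res$objective,
                 objective_path = res$objective_path,
                 fitted.values = fitted, residuals = y - fitted,
                 nobs = n),
            class = "enet")
}

#' @export
print.enet <- function(x, ...) {
  cat("Weighted elastic net (alpha =", format(x$alpha),
      ", lambda =", format(x$lambda), ")\n")
  cat(sprintf("  %d features, %d nonzero; intercept %.4g\n",
              length(x$coefficients), sum(x$coefficients != 0), x$intercept))
  cat(sprintf("  converged in %d sweeps, objective %.6g\n",
              x$sweeps, x$objective))
  invisible(x)
}

#' @export
coef.enet <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' Predict continuous scores from a fitted elastic net
#'
#' The exact linear form `x %*% W + b`; no clipping is applied.
#'
#' @param object An `enet` fit.
#' @param newx Matrix with the same columns (in order) as the training
#'   design matrix.
#' @param ... Unused.
#' @return Numeric vector of scores.
#' @export
predict.enet <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  if (ncol(newx) != length(object$coefficients))
    stop("newx has ", ncol(newx), " columns; model expects ",
         length(object$coefficients))
  drop(newx %*% object$coefficients) + object$intercept
}

#' @export
residuals.enet <- function(object, ...) object$residuals

#' Per-subject training weights from a Gensini threshold
#'
#' Subjects whose modified Gensini score is at or above `threshold` receive
#' weight `factor`; all others weight 1. Used to emphasise high-score (more
#' diseased) subjects during elastic-net training.
#'
#' @param y Modified Gensini scores.
#' @param threshold Cutoff on `y`.
#' @param factor Upweight factor, >= 1. `factor = 1` is a no-op.
#' @return Weight vector of the same length as `y`.
#' @export
apply_upweighting <- function(y, threshold, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || factor < 1)
    stop("factor must be a single number >= 1")
  ifelse(y >= threshold, factor, 1)
}
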