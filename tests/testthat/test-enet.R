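test_that("lambda = 0 reduces to ordinary least squares on an exact-fit problem", {
  x <- cbind(f = c(1, 2, 3))
  fit <- enet_fit(x, c(2, 4, 6), alpha = 1, lambda = 0,
                  standardize = FALSE)
  expect_equal(unname(fit$coefficients), 2, tolerance = 1e-10)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
  expect_equal(predict(fit, x), c(2, 4, 6), tolerance = 1e-10)
})

test_that("pure ridge matches the (X'X + 0.5 lambda I) closed form", {
  set.seed(21)
  for (rep in 1:10) {
    n <- 40; p <- 6
    x <- scale(matrix(rnorm(n * p), n, p), scale = FALSE)
    y <- drop(x %*% rnorm(p)) + rnorm(n)
    y <- y - mean(y)
    lam <- 10^runif(1, -2, 2)
    fit <- enet_fit(x, y, alpha = 0, lambda = lam, standardize = FALSE,
                    tol = 1e-10)
    w_ref <- solve(crossprod(x) + 0.5 * lam * diag(p), crossprod(x, y))
    expect_lt(max(abs(fit$coefficients - drop(w_ref))), 1e-6)
  }
})

test_that("the lasso on one unit-norm feature is the analytic soft threshold", {
  # centred x with x'x = 1 and x'y = 3; loss |y - xw|^2 + 2|w| has
  # minimiser S(3, 1) = 2
  x <- c(-1, 0, 1) / sqrt(2)
  y <- 3 * x
  fit <- enet_fit(cbind(x), y, alpha = 1, lambda = 2, standardize = FALSE,
                  tol = 1e-12)
  expect_equal(unname(fit$coefficients), 2, tolerance = 1e-8)
})

test_that("solutions agree with glmnet once lambda is rescaled to the printed loss", {
  skip_if_not_installed("glmnet")
  set.seed(31)
  worst <- 0
  for (rep in 1:50) {
    n <- 40; p <- 10
    x <- matrix(rnorm(n * p), n, p)
    y <- drop(x[, 1:3] %*% c(1, -2, 0.5)) + rnorm(n)
    # glmnet rescales the response internally (even with
    # standardize = FALSE), which multiplies the effective L1 strength by
    # sd(y); giving it a unit-variance response makes the lambda mapping
    # below exact
    y <- (y - mean(y)) / sqrt(mean((y - mean(y))^2))
    al <- runif(1)
    lam <- 10^runif(1, -1, 1.5)
    fit <- enet_fit(x, y, alpha = al, lambda = lam, standardize = FALSE,
                    tol = 1e-10, max_sweeps = 1e5)
    # glmnet minimises 1/(2n) RSS + lam_g ((1-a)/2 |w|_2^2 + a |w|_1):
    # identical solution at lam_g = lam / (2n)
    g <- glmnet::glmnet(x, y, alpha = al, lambda = lam / (2 * n),
                        standardize = FALSE, thresh = 1e-14)
    wg <- as.numeric(g$beta)
    worst <- max(worst, max(abs(fit$coefficients - wg)))
  }
  expect_lt(worst, 1e-5)
})

test_that("the penalised objective is non-increasing across sweeps", {
  set.seed(41)
  x <- matrix(rnorm(60 * 8), 60, 8)
  x[, 5] <- x[, 4] + rnorm(60, sd = 0.05)   # correlated pair
  y <- drop(x %*% c(1, 0, -1, 2, 0, 0, 0.5, 0)) + rnorm(60)
  for (al in c(0, 0.5, 1)) {
    fit <- enet_fit(x, y, alpha = al, lambda = 3, track_objective = TRUE)
    expect_true(all(diff(fit$objective_path) <= 1e-9))
  }
})

test_that("the number of nonzero weights is non-increasing in lambda", {
  set.seed(51)
  x <- matrix(rnorm(50 * 12), 50, 12)
  y <- drop(x %*% c(2, -1, 1, rep(0, 9))) + rnorm(50)
  nz <- vapply(10^seq(-2, 3, length.out = 12), function(lam)
    sum(abs(enet_fit(x, y, alpha = 0.7, lambda = lam)$coefficients) >
          1e-10), numeric(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("with n >= 2p the small-lambda fit approaches OLS", {
  set.seed(61)
  n <- 40; p <- 10
  x <- matrix(rnorm(n * p), n, p)
  y <- drop(x %*% rnorm(p)) + rnorm(n)
  fit <- enet_fit(x, y, alpha = 0.5, lambda = 1e-8, standardize = FALSE,
                  tol = 1e-10, max_sweeps = 1e5)
  ols <- stats::lm.fit(cbind(1, x), y)$coefficients
  expect_lt(max(abs(fit$coefficients - ols[-1])), 1e-5)
  expect_lt(abs(fit$intercept - ols[1]), 1e-5)
})

test_that("subject weights enter the loss as stated", {
  # weighted OLS limit: weights act like replication
  x <- cbind(c(1, 2, 3, 10))
  y <- c(2, 4, 6, 0)
  w <- c(1, 1, 1, 0)       # zero weight removes the outlier entirely
  fit <- enet_fit(x, y, weights = w, alpha = 1, lambda = 0,
                  standardize = FALSE)
  expect_equal(unname(fit$coefficients), 2, tolerance = 1e-8)
  expect_equal(fit$intercept, 0, tolerance = 1e-8)
})

test_that("upweighting builds the threshold-factor weight vector", {
  expect_equal(apply_upweighting(c(0, 1, 3), 2, 4), c(1, 1, 4))
  expect_equal(apply_upweighting(c(0, 1, 3), 2, 1), c(1, 1, 1))
  expect_equal(apply_upweighting(c(0, 1, 3), -1, 6), c(6, 6, 6))
  expect_equal(apply_upweighting(c(0, 2, 3), 2, 5), c(1, 5, 5))  # >= rule
  expect_error(apply_upweighting(c(0, 1), 0.5, 0.5), ">= 1")
})

test_that("zero-variance features are pinned to zero with a warning", {
  set.seed(71)
  x <- cbind(rnorm(30), rep(2, 30), rnorm(30))
  y <- x[, 1] + rnorm(30, sd = 0.1)
  expect_warning(fit <- enet_fit(x, y, alpha = 0.5, lambda = 1),
                 "zero-variance")
  expect_identical(unname(fit$coefficients[2]), 0)
})

test_that("non-convergence raises a classed error carrying the objective", {
  set.seed(81)
  x <- matrix(rnorm(40 * 10), 40, 10)
  y <- rnorm(40)
  err <- tryCatch(
    enet_fit(x, y, alpha = 0.1, lambda = 1e-6, tol = 1e-14,
             max_sweeps = 3L),
    cadnet_nonconvergence = function(e) e)
  expect_s3_class(err, "cadnet_nonconvergence")
  expect_true(is.finite(err$objective))
})

test_that("prediction is the exact linear form", {
  set.seed(91)
  x <- matrix(rnorm(20 * 4), 20, 4)
  fit <- enet_fit(x, rnorm(20), alpha = 0.5, lambda = 5)
  # constant model check
  cfit <- fit; cfit$coefficients[] <- 0; cfit$intercept <- 1.7
  expect_equal(predict(cfit, x), rep(1.7, 20))
  # linearity: perturbing one feature moves the score by w_j * delta
  x2 <- x; x2[3, 2] <- x2[3, 2] + 1.5
  d <- predict(fit, x2) - predict(fit, x)
  expect_equal(d[3], unname(fit$coefficients[2]) * 1.5, tolerance = 1e-12)
  expect_equal(d[-3], rep(0, 19))
})
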