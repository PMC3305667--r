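test_that("standardize_predictors centers and scales with divisor n", {
  X <- cbind(a = rep(c(0, 1), each = 10), b = rbinom(20, 1, 0.5))
  while (sd(X[, "b"]) == 0) X[, "b"] <- rbinom(20, 1, 0.5)
  std <- standardize_predictors(X)
  # balanced 0/1 column has population sd 0.5, so values map to +/- 1
  expect_equal(sort(unique(std$x[, "a"])), c(-1, 1))
  expect_equal(colMeans(std$x), c(a = 0, b = 0))
  expect_equal(colMeans(std$x^2), c(a = 1, b = 1))
  # idempotence
  std2 <- standardize_predictors(std$x)
  expect_equal(std2$x, std$x, tolerance = 1e-12)
  # invertibility
  back <- sweep(sweep(std$x, 2, std$scale, "*"), 2, std$center, "+")
  expect_equal(back, X, ignore_attr = TRUE)
  X[, 2] <- 0
  expect_error(standardize_predictors(X), "constant.*b")
})

test_that("lambda_grid spans lambda_max down to lambda_max/1000", {
  pr <- random_problem(1, n = 60, q = 3)
  g <- lambda_grid(pr$y, pr$X)
  expect_length(g, 100)
  expect_true(all(diff(g) < 0))
  expect_equal(g[100] / g[1], 1e-3)
  # grid head gives an empty active set, by definition of lambda_max
  fit <- fit_l1_logistic(pr$y, pr$X, g[1])
  expect_length(fit$active_set, 0)
})

test_that("fully penalized fit is the intercept-only model", {
  pr <- random_problem(2, n = 80, q = 4)
  lmax <- lambda_grid(pr$y, pr$X)[1]
  fit <- fit_l1_logistic(pr$y, pr$X, lmax * 2)
  expect_true(all(fit$coefficients == 0))
  expect_equal(fit$intercept, qlogis(mean(pr$y)))
  expect_lte(fit$loglik, 0)
})

test_that("solutions satisfy the KKT conditions at 1e-6", {
  worst <- 0
  for (r in 1:30) {
    pr <- random_problem(100 + r, n = sample(30:60, 1), q = sample(2:5, 1))
    g <- lambda_grid(pr$y, pr$X)
    lam <- g[1] * runif(1, 0.05, 0.8)
    fit <- fit_l1_logistic(pr$y, pr$X, lam)
    expect_identical(fit$active_set,
                     names(fit$coefficients)[fit$coefficients != 0])
    worst <- max(worst, kkt_residual(fit, pr$y, pr$X))
  }
  expect_lt(worst, 1e-6)
})

test_that("unpenalized fit matches glm", {
  for (r in 1:10) {
    pr <- random_problem(200 + r, n = 80, q = 3, beta_sd = 0.5)
    fit <- fit_l1_logistic(pr$y, pr$X, 0)
    ref <- glm(pr$y ~ pr$X, family = binomial)
    expect_lt(max(abs(c(fit$intercept, fit$coefficients) - coef(ref))), 1e-5)
  }
})

test_that("objective value matches a brute-force minimizer", {
  for (r in 1:5) {
    pr <- random_problem(300 + r, n = 50, q = 3)
    lam <- lambda_grid(pr$y, pr$X)[1] * runif(1, 0.1, 0.6)
    fit <- fit_l1_logistic(pr$y, pr$X, lam)
    ours <- pen_objective(pr$y, pr$X, fit$intercept, fit$coefficients, lam)
    oracle <- oracle_min_objective(pr$y, pr$X, lam, seed = r)
    expect_lte(ours, oracle + 1e-4)
  }
})

test_that("regularization path starts empty and reaches the MLE region", {
  pr <- random_problem(42, n = 200, q = 3, beta_sd = 0.6)
  g <- lambda_grid(pr$y, pr$X)
  path <- regularization_path(pr$y, pr$X, g)
  expect_equal(path$df[1], 0)
  ref <- glm(pr$y ~ pr$X, family = binomial)
  expect_lt(max(abs(path$beta[, 100] - coef(ref)[-1])), 0.05)
  # penalized objective at the solution is non-increasing along the path
  obj <- vapply(seq_along(g), function(k) {
    -path$loglik[k] + g[k] * sum(abs(path$beta[, k]))
  }, numeric(1))
  expect_true(all(diff(obj) < 1e-8))
})

test_that("active-set sizes grow along the path on simulated graph data", {
  d <- m6_data(500, seed = 77)
  steps_ok <- steps <- 0
  for (a in 1:6) {
    y <- d[, a]
    Xs <- standardize_predictors(d[, -a])$x
    path <- regularization_path(y, Xs)
    steps_ok <- steps_ok + sum(diff(path$df) >= 0)
    steps <- steps + length(path$df) - 1
  }
  expect_gte(steps_ok / steps, 0.95)
})

test_that("information criteria select the argmin penalty, ties to larger", {
  pr <- random_problem(55, n = 100, q = 4, beta_sd = 0.7)
  g <- lambda_grid(pr$y, pr$X)
  path <- regularization_path(pr$y, pr$X, g)
  lam_aic <- select_penalty_ic(pr$y, pr$X, g, "aic")
  lam_bic <- select_penalty_ic(pr$y, pr$X, g, "bic")
  aic <- -2 * path$loglik + 2 * path$df
  bic <- -2 * path$loglik + path$df * log(100)
  expect_equal(lam_aic, g[which.min(aic)])
  expect_equal(lam_bic, g[which.min(bic)])
  expect_true(lam_aic %in% g && lam_bic %in% g)
})

test_that("BIC selects neighborhoods no larger than AIC on graph data", {
  smaller <- logical(0)
  for (r in 1:20) {
    d <- gibbs_sample(preset_structure("m6"), 500, burn_in = 500,
                      spacing = 3, seed = 400 + r)
    for (a in 1:6) {
      y <- d[, a]
      Xs <- standardize_predictors(d[, -a])$x
      g <- lambda_grid(y, Xs)
      path <- regularization_path(y, Xs, g)
      sz <- function(lam) path$df[which.min(abs(g - lam))]
      smaller <- c(smaller, sz(select_penalty_ic(y, Xs, g, "bic")) <=
                             sz(select_penalty_ic(y, Xs, g, "aic")))
    }
  }
  expect_gte(mean(smaller), 0.9)
})

test_that("cross-validation picks large penalties under the null", {
  empty <- 0
  for (r in 1:10) {
    set.seed(600 + r)
    X <- matrix(rbinom(400 * 4, 1, 0.5), 400, 4)
    y <- rbinom(400, 1, 0.5)
    Xs <- standardize_predictors(X)$x
    g <- lambda_grid(y, Xs)
    lam <- select_penalty_cv(y, Xs, g, folds = 10, seed = r)
    expect_true(lam %in% g)
    path <- regularization_path(y, Xs, g)
    if (path$df[which.min(abs(g - lam))] <= 1) empty <- empty + 1
  }
  expect_gte(empty / 10, 0.8)
  pr <- random_problem(9, n = 40, q = 3)
  expect_error(select_penalty_cv(pr$y, pr$X, folds = 1), "folds")
})

test_that("penalty_for_size honours its contract", {
  pr <- random_problem(71, n = 150, q = 4)
  g <- lambda_grid(pr$y, pr$X)
  path <- regularization_path(pr$y, pr$X, g)
  for (l in 1:3) {
    lam <- penalty_for_size(pr$y, pr$X, g, l)
    expect_true(lam %in% g)
    k <- which.min(abs(g - lam))
    expect_gte(path$df[k], l)
    if (k > 1) expect_true(all(path$df[1:(k - 1)] < l))
  }
  expect_error(penalty_for_size(pr$y, pr$X, g, 0), "l >= 1")
  # a single dominant predictor is selected alone at l = 1
  set.seed(4)
  X <- matrix(rbinom(600, 1, 0.5), 200, 3)
  Xs <- standardize_predictors(X)$x
  y <- rbinom(200, 1, plogis(2.5 * Xs[, 2]))
  g2 <- lambda_grid(y, Xs)
  lam1 <- penalty_for_size(y, Xs, g2, 1)
  fit <- fit_l1_logistic(y, Xs, lam1)
  expect_identical(fit$active_set, "x2")
})

test_that("null fits are empty at lambda_max and admit only the top scorer below it", {
  # lambda_max is the entry point of the largest-score predictor: the fit
  # is empty at or above it, and that predictor is active at any smaller
  # penalty (forced by the stationarity conditions)
  for (r in 1:20) {
    set.seed(800 + r)
    X <- matrix(rbinom(100 * 4, 1, 0.5), 100, 4)
    if (any(apply(X, 2, sd) == 0)) next
    y <- rbinom(100, 1, 0.5)
    if (length(unique(y)) < 2) next
    Xs <- standardize_predictors(X)$x
    colnames(Xs) <- paste0("x", 1:4)
    scores <- abs(crossprod(Xs, y - mean(y)))
    lmax <- lambda_grid(y, Xs)[1]
    expect_length(fit_l1_logistic(y, Xs, lmax)$active_set, 0)
    fit <- fit_l1_logistic(y, Xs, lmax / 2)
    expect_true(colnames(Xs)[which.max(scores)] %in% fit$active_set)
  }
})
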