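# Shared fixtures and independent oracles for the test suite.

# Cache expensive simulated datasets across test files.
.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, expr, envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

m6_data <- function(n = 1000, seed = 101) {
  cached(paste0("m6_", n, "_", seed),
         gibbs_sample(preset_structure("m6"), n, seed = seed))
}

# A small well-conditioned logistic problem with binary predictors.
random_problem <- function(seed, n = 50, q = 3, beta_sd = 0.8) {
  set.seed(seed)
  repeat {
    X <- matrix(rbinom(n * q, 1, runif(1, 0.3, 0.7)), n, q)
    if (all(apply(X, 2, sd) > 0)) break
  }
  Xs <- standardize_predictors(X)$x
  y <- rbinom(n, 1, plogis(rnorm(1, 0, 0.3) + Xs %*% rnorm(q, 0, beta_sd)))
  if (length(unique(y)) < 2) return(random_problem(seed + 5000, n, q, beta_sd))
  list(y = y, X = Xs)
}

# Penalized objective: negative log-likelihood + lambda * sum |beta|.
pen_objective <- function(y, X, intercept, beta, lambda) {
  eta <- as.numeric(intercept + X %*% beta)
  -sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta))))) +
    lambda * sum(abs(beta))
}

# Independent brute-force minimizer of the penalized objective:
# multi-start Nelder-Mead over (intercept, beta). Returns the best
# objective value found.
oracle_min_objective <- function(y, X, lambda, starts = 8, seed = 1) {
  q <- ncol(X)
  f <- function(par) pen_objective(y, X, par[1], par[-1], lambda)
  set.seed(seed)
  best <- Inf
  for (s in seq_len(starts)) {
    par0 <- if (s == 1) rep(0, q + 1) else rnorm(q + 1, 0, 0.5)
    opt <- optim(par0, f, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-12))
    best <- min(best, opt$value)
  }
  best
}

# Random undirected graph over the given nodes.
random_graph <- function(nodes, prob = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < prob
  bgm_graph(nodes, pairs[keep, , drop = FALSE])
}

# Brute-force confusion counts by looping over all unordered pairs.
brute_confusion <- function(est, truth) {
  nodes <- sort(truth$nodes)
  tp <- fp <- tn <- fn <- 0L
  has_edge <- function(g, a, b) {
    any(g$edges[, 1] == min(a, b) & g$edges[, 2] == max(a, b))
  }
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (i >= j) next
      e <- has_edge(est, nodes[i], nodes[j])
      t_ <- has_edge(truth, nodes[i], nodes[j])
      if (e && t_) tp <- tp + 1L
      if (e && !t_) fp <- fp + 1L
      if (!e && t_) fn <- fn + 1L
      if (!e && !t_) tn <- tn + 1L
    }
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}
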