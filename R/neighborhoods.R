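#' Node-wise neighborhoods by single L1-penalized logistic regressions
#'
#' For each variable `a`, regresses `a` on all remaining variables
#' (standardized) with an L1 penalty chosen by the given rule, and takes
#' the active set as the estimated neighborhood `ne_a`. Constant columns
#' cannot be regressed on and are dropped from the dataset with a warning
#' before estimation.
#'
#' @param data a [binary_dataset()] (or plain 0/1 matrix with column
#'   names); at least 3 variables.
#' @param penalty penalty-selection rule: `"cv"`, `"aic"`, `"bic"`, or
#'   `"size"` (target neighborhood size `l`, see [penalty_for_size()]).
#' @param l target neighborhood size, required when `penalty = "size"`.
#' @param folds CV fold count (used when `penalty = "cv"`).
#' @param seed integer seed for the CV fold assignment (per-node seeds are
#'   derived as `seed + node index`).
#' @return an object of class `bgm_neighborhoods`: list with `nodes`,
#'   `selected` (named list of neighbor label vectors), `lambda` (named
#'   vector of per-node penalties), `frequencies` (`NULL` for single-LASSO
#'   fits), `method`, `params`.
#' @export
lasso_neighborhoods <- function(data, penalty = c("cv", "aic", "bic", "size"),
                                l = NULL, folds = 10, seed = NULL) {
  penalty <- match.arg(penalty)
  data <- prepare_dataset(data)
  nodes <- colnames(data)
  p <- length(nodes)
  if (penalty == "size") {
    stopifnot(!is.null(l), l >= 1, l <= p - 1)
  }
  selected <- vector("list", p)
  names(selected) <- nodes
  lambda <- setNames(numeric(p), nodes)
  for (a in seq_len(p)) {
    y <- data[, a]
    Xs <- standardize_predictors(data[, -a, drop = FALSE])$x
    grid <- lambda_grid(y, Xs)
    path <- regularization_path(y, Xs, grid)
    lam <- switch(penalty,
      cv = select_penalty_cv(y, Xs, grid, folds = folds,
                             seed = if (is.null(seed)) NULL else seed + a),
      aic = select_penalty_ic(y, Xs, grid, "aic"),
      bic = select_penalty_ic(y, Xs, grid, "bic"),
      size = penalty_for_size(y, Xs, grid, l)
    )
    k <- which.min(abs(grid - lam))
    selected[[a]] <- rownames(path$beta)[path$beta[, k] != 0]
    lambda[a] <- lam
  }
  new_neighborhoods(
    nodes, selected, lambda,
    method = paste0("lasso-", if (penalty == "size") paste0("size:", l) else penalty),
    params = list(penalty = penalty, l = l, folds = folds, seed = seed)
  )
}

new_neighborhoods <- function(nodes, selected, lambda, method, params,
                              frequencies = NULL, pi_cut = NULL, B = NULL) {
  structure(
    list(nodes = nodes, selected = selected, lambda = lambda,
         frequencies = frequencies, pi_cut = pi_cut, B = B,
         method = method, params = params),
    class = "bgm_neighborhoods"
  )
}

#' @export
print.bgm_neighborhoods <- function(x, ...) {
  cat("Neighborhood set (", x$method, "): ", length(x$nodes), " nodes, ",
      sum(lengths(x$selected)), " directed selections\n", sep = "")
  invisible(x)
}

# Validate/convert input data and drop constant columns with a warning.
prepare_dataset <- function(data) {
  if (!inherits(data, "bgm_dataset")) data <- binary_dataset(as.matrix(data))
  keep <- apply(data, 2, function(col) length(unique(col)) > 1L)
  if (!all(keep)) {
    warning("dropping constant column(s): ",
            paste(colnames(data)[!keep], collapse = ", "))
    data <- binary_dataset(unclass(data)[, keep, drop = FALSE],
                           provenance = attr(data, "provenance"))
  }
  if (ncol(data) < 3L) {
    stop("need at least 3 non-constant variables to estimate a graph",
         call. = FALSE)
  }
  data
}

#' Node-wise neighborhoods by the Bolasso
#'
#' Bootstrap-aggregated neighborhood selection: for each of `B` bootstrap
#' resamples of whole observations, every node's penalized regression is
#' refit and the active set recorded. The selection frequency `mu[b, a]`
#' is the fraction of resamples in which `b` entered the neighborhood of
#' `a`, and the aggregated neighborhood keeps `{b : mu[b, a] >= pi_cut}`.
#' Frequencies are retained in the result so other thresholds can be
#' applied with [apply_cut()] without refitting.
#'
#' Two penalty protocols are available inside the bootstrap loop:
#' \describe{
#'   \item{size rule, `retune = TRUE` (default)}{each bootstrap fit
#'     re-applies [penalty_for_size()] on the resample, i.e. keeps the
#'     first `l` (or more, on ties) variables entering that resample's
#'     regularization path. Re-tuning makes the size rule meaningful under
#'     resampling: a penalty frozen at the value where the l-th variable
#'     enters the original path sits exactly at that variable's selection
#'     boundary, so its bootstrap frequency hovers near 1/2 by
#'     construction and aggregation degenerates.}
#'   \item{fixed penalty, `retune = FALSE` (forced for `penalty = "cv"`)}{
#'     the per-node penalty is chosen once on the original data and reused
#'     for every bootstrap refit.}
#' }
#'
#' Resamples draw `n` rows with replacement, seeded `seed + b` for
#' resample `b`; the same resamples are shared by all nodes. A resample in
#' which a node's outcome or any predictor column is constant contributes
#' an empty active set for that node (the denominator stays `B`).
#'
#' @inheritParams lasso_neighborhoods
#' @param B number of bootstrap resamples (>= 1).
#' @param penalty `"size"` (default) or `"cv"`.
#' @param pi_cut selection-frequency threshold in (0, 1].
#' @param seed integer seed for the bootstrap resamples.
#' @param retune re-select the size-rule penalty within each bootstrap
#'   resample (default `TRUE` for `penalty = "size"`; not available for
#'   `"cv"`).
#' @return a `bgm_neighborhoods` whose `frequencies` field is the p x p
#'   matrix `mu` (rows: candidate neighbor, columns: node).
#' @export
bolasso_neighborhoods <- function(data, B, penalty = c("size", "cv"),
                                  l = NULL, pi_cut = 0.9, folds = 10,
                                  seed = 1, retune = NULL) {
  penalty <- match.arg(penalty)
  stopifnot(B >= 1, pi_cut > 0, pi_cut <= 1)
  retune <- retune %||% (penalty == "size")
  if (retune && penalty != "size") {
    stop("`retune` is only available for the size penalty rule",
         call. = FALSE)
  }
  data <- prepare_dataset(data)
  nodes <- colnames(data)
  p <- length(nodes)
  if (penalty == "size") stopifnot(!is.null(l), l >= 1, l <= p - 1)
  if (retune) {
    lambda <- rep(NA_real_, p)
    sel <- bolasso_selections_size(data, B, l, seed = seed)
  } else {
    lambda <- node_lambdas(data, penalty, l = l, folds = folds, seed = seed)
    sel <- bolasso_selections(data, B, matrix(lambda, ncol = 1), seed = seed)
  }
  mu <- colMeans(sel)[, , 1]  # p x p: [candidate, node]
  dimnames(mu) <- list(nodes, nodes)
  nb <- threshold_frequencies(mu, pi_cut)
  new_neighborhoods(
    nodes, nb, setNames(lambda, nodes),
    method = if (penalty == "cv") "bolasso-cv" else "bolasso",
    params = list(B = B, penalty = penalty, l = l, pi_cut = pi_cut,
                  folds = folds, seed = seed, retune = retune,
                  degenerate_fits = attr(sel, "degenerate")),
    frequencies = mu, pi_cut = pi_cut, B = B
  )
}

# Per-node penalty on the original data.
node_lambdas <- function(data, penalty, l = NULL, folds = 10, seed = NULL) {
  p <- ncol(data)
  vapply(seq_len(p), function(a) {
    y <- data[, a]
    Xs <- standardize_predictors(data[, -a, drop = FALSE])$x
    grid <- lambda_grid(y, Xs)
    switch(penalty,
      size = penalty_for_size(y, Xs, grid, l),
      cv = select_penalty_cv(y, Xs, grid, folds = folds,
                             seed = if (is.null(seed)) NULL else seed + a),
      aic = select_penalty_ic(y, Xs, grid, "aic"),
      bic = select_penalty_ic(y, Xs, grid, "bic")
    )
  }, numeric(1))
}

# Bootstrap selection indicators. `lambda_mat` is p x nl: one penalty per
# node and per target setting (several settings share the same resamples
# and glmnet path call). Returns a logical array [B, p(candidate),
# p(node), nl]; attribute "degenerate" counts skipped (node, resample)
# fits.
bolasso_selections <- function(data, B, lambda_mat, seed = 1) {
  n <- nrow(data)
  p <- ncol(data)
  nl <- ncol(lambda_mat)
  sel <- array(FALSE, dim = c(B, p, p, nl))
  degenerate <- 0L
  for (b in seq_len(B)) {
    idx <- with_seed(seed + b, sample.int(n, n, replace = TRUE))
    boot <- unclass(data)[idx, , drop = FALSE]
    const <- apply(boot, 2, function(col) all(col == col[1]))
    for (a in seq_len(p)) {
      # a degenerate resample (constant outcome or predictor) contributes
      # an empty active set, keeping the frequency denominator at B
      if (any(const)) {
        degenerate <- degenerate + 1L
        next
      }
      y <- boot[, a]
      Xs <- standardize_predictors(boot[, -a, drop = FALSE])$x
      lams <- sort(unique(lambda_mat[a, ]), decreasing = TRUE)
      fit <- suppressWarnings(glmnet_fit(y, Xs, lams))
      beta <- glmnet_coefs(fit)$beta
      for (k in seq_len(nl)) {
        col <- which.min(abs(lams - lambda_mat[a, k]))
        active <- beta[, col] != 0
        sel[b, seq_len(p)[-a], a, k] <- active
      }
    }
  }
  structure(sel, degenerate = degenerate)
}

# Bootstrap selection indicators with the size rule re-tuned per resample:
# one truncated regularization path per (resample, node), reading off the
# active set at the first grid point with >= l active variables for every
# target size in `l_vec`. Returns a logical array [B, p(candidate),
# p(node), length(l_vec)]; attribute "degenerate" counts skipped fits.
bolasso_selections_size <- function(data, B, l_vec, seed = 1) {
  n <- nrow(data)
  p <- ncol(data)
  nl <- length(l_vec)
  stopifnot(all(l_vec >= 1), all(l_vec <= p - 1))
  sel <- array(FALSE, dim = c(B, p, p, nl))
  degenerate <- 0L
  dfcap <- max(l_vec) + 2L
  for (b in seq_len(B)) {
    idx <- with_seed(seed + b, sample.int(n, n, replace = TRUE))
    boot <- unclass(data)[idx, , drop = FALSE]
    const <- apply(boot, 2, function(col) all(col == col[1]))
    for (a in seq_len(p)) {
      if (any(const)) {
        degenerate <- degenerate + 1L
        next
      }
      y <- boot[, a]
      Xs <- standardize_predictors(boot[, -a, drop = FALSE])$x
      # glmnet's automatic path equals lambda_grid(): 100 log-spaced
      # penalties from lambda_max down to lambda_max * 1e-3; dfmax stops
      # the path shortly after the largest target size is reached
      fit <- suppressWarnings(
        glmnet::glmnet(Xs, y, family = "binomial", standardize = FALSE,
                       nlambda = 100, lambda.min.ratio = 1e-3,
                       dfmax = dfcap)
      )
      df <- fit$df
      if (max(df) < max(l_vec) && length(df) < 100L) {
        # path ended early (deviance plateau); refit without truncation
        grid <- lambda_grid(y, Xs)
        fit <- suppressWarnings(glmnet_fit(y, Xs, grid))
        df <- fit$df
      }
      for (k in seq_len(nl)) {
        j <- which(df >= l_vec[k])[1]
        if (is.na(j)) j <- length(df)
        active <- abs(fit$beta[, j]) > 1e-10
        sel[b, seq_len(p)[-a], a, k] <- active
      }
    }
  }
  structure(sel, degenerate = degenerate)
}

threshold_frequencies <- function(mu, pi_cut) {
  nodes <- colnames(mu)
  nb <- lapply(seq_along(nodes), function(a) {
    nodes[mu[, a] >= pi_cut - 1e-9 & seq_along(nodes) != a]
  })
  names(nb) <- nodes
  nb
}

#' Re-threshold Bolasso selection frequencies
#'
#' Applies a new inclusion threshold to the stored frequency matrix of a
#' Bolasso neighborhood set, without refitting anything.
#'
#' @param nbhd a `bgm_neighborhoods` with a `frequencies` field.
#' @param pi_cut new threshold in (0, 1].
#' @return a `bgm_neighborhoods` with updated selections.
#' @export
apply_cut <- function(nbhd, pi_cut) {
  stopifnot(inherits(nbhd, "bgm_neighborhoods"),
            pi_cut > 0, pi_cut <= 1)
  if (is.null(nbhd$frequencies)) {
    stop("neighborhood set has no stored selection frequencies", call. = FALSE)
  }
  nbhd$selected <- threshold_frequencies(nbhd$frequencies, pi_cut)
  nbhd$pi_cut <- pi_cut
  nbhd$params$pi_cut <- pi_cut
  nbhd
}

#' Combine node-wise neighborhoods into an undirected edge set
#'
#' The AND-rule keeps edge (a, b) when each node is in the other's
#' neighborhood; the OR-rule when at least one is. The AND edge set is
#' always a subset of the OR edge set. For Bolasso neighborhoods the
#' resulting graph carries per-edge selection frequencies (the min of the
#' two directed frequencies under AND, the max under OR).
#'
#' @param nbhd a `bgm_neighborhoods`.
#' @param rule `"OR"` (default, as in the Bolasso algorithm) or `"AND"`.
#' @return a [bgm_graph()] with estimation metadata.
#' @export
combine_edges <- function(nbhd, rule = c("OR", "AND")) {
  rule <- match.arg(toupper(rule), c("OR", "AND"))
  stopifnot(inherits(nbhd, "bgm_neighborhoods"))
  nodes <- nbhd$nodes
  p <- length(nodes)
  inset <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  for (a in nodes) inset[nbhd$selected[[a]], a] <- TRUE
  keep <- if (rule == "AND") inset & t(inset) else inset | t(inset)
  idx <- which(keep & upper.tri(keep), arr.ind = TRUE)
  edges <- cbind(nodes[idx[, 1]], nodes[idx[, 2]])
  freqs <- NULL
  if (!is.null(nbhd$frequencies) && nrow(idx) > 0L) {
    mu <- nbhd$frequencies
    f <- if (rule == "AND") {
      pmin(mu[idx], t(mu)[idx])
    } else {
      pmax(mu[idx], t(mu)[idx])
    }
    freqs <- setNames(f, edge_key(nodes[idx[, 1]], nodes[idx[, 2]]))
  }
  bgm_graph(nodes, edges, method = nbhd$method, rule = rule,
            params = nbhd$params, frequencies = freqs)
}

#' Estimate a binary graphical model
#'
#' One-call front end dispatching to [lasso_neighborhoods()] or
#' [bolasso_neighborhoods()] and combining the result with
#' [combine_edges()].
#'
#' @param data a [binary_dataset()] or 0/1 matrix.
#' @param method `"lasso-cv"`, `"lasso-aic"`, `"lasso-bic"`, `"bolasso"`
#'   (fixed-size penalty; requires `B`, `pi_cut`, `l`), or `"bolasso-cv"`
#'   (cross-validated penalty; requires `B`, `pi_cut`).
#' @param rule `"OR"` (default) or `"AND"`.
#' @param B,pi_cut,l,folds,retune method parameters (see the underlying
#'   functions).
#' @param seed integer seed used by the bootstrap and CV steps.
#' @return a [bgm_graph()] recording the full parameterization.
#' @examples
#' d <- gibbs_sample(preset_structure("m6"), 300, burn_in = 200, seed = 7)
#' estimate_graph(d, "lasso-bic", rule = "AND")
#' @export
estimate_graph <- function(data,
                           method = c("lasso-cv", "lasso-aic", "lasso-bic",
                                      "bolasso", "bolasso-cv"),
                           rule = c("OR", "AND"), B = NULL, pi_cut = NULL,
                           l = NULL, folds = 10, seed = 1, retune = NULL) {
  method <- match.arg(method)
  rule <- match.arg(toupper(rule), c("OR", "AND"))
  need <- function(value, field) {
    if (is.null(value)) {
      stop("method ", dQuote(method, FALSE), " requires parameter `", field,
           "`", call. = FALSE)
    }
  }
  nbhd <- switch(method,
    "lasso-cv" = lasso_neighborhoods(data, "cv", folds = folds, seed = seed),
    "lasso-aic" = lasso_neighborhoods(data, "aic"),
    "lasso-bic" = lasso_neighborhoods(data, "bic"),
    "bolasso" = {
      need(B, "B"); need(pi_cut, "pi_cut"); need(l, "l")
      bolasso_neighborhoods(data, B = B, penalty = "size", l = l,
                            pi_cut = pi_cut, seed = seed, retune = retune)
    },
    "bolasso-cv" = {
      need(B, "B"); need(pi_cut, "pi_cut")
      bolasso_neighborhoods(data, B = B, penalty = "cv", pi_cut = pi_cut,
                            folds = folds, seed = seed)
    }
  )
  g <- combine_edges(nbhd, rule)
  g$params <- c(g$params, list(method = method, rule = rule, seed = seed))
  g
}
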