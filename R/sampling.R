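#' Binary dataset container
#'
#' An n x p matrix of 0/1 observations with unique column labels and a
#' free-text provenance record (generator settings or source file).
#'
#' @param data numeric or integer matrix with entries in {0, 1}.
#' @param labels character vector of p unique variable names; defaults to
#'   the column names of `data`.
#' @param provenance single string describing where the data came from.
#' @return an object of class `bgm_dataset` (an integer matrix with a
#'   `provenance` attribute).
#' @export
binary_dataset <- function(data, labels = NULL, provenance = "unspecified") {
  if (!is.matrix(data)) stop("`data` must be a matrix", call. = FALSE)
  if (nrow(data) < 1L) stop("dataset needs at least one row", call. = FALSE)
  if (anyNA(data) || !all(data %in% c(0, 1))) {
    bad <- which(is.na(data) | !(data %in% c(0, 1)), arr.ind = TRUE)[1, ]
    stop(sprintf("non-binary entry at row %d, column %d", bad[1], bad[2]),
         call. = FALSE)
  }
  labels <- labels %||% colnames(data) %||% paste0("V", seq_len(ncol(data)))
  if (length(labels) != ncol(data) || anyDuplicated(labels)) {
    stop("`labels` must be ", ncol(data), " unique names", call. = FALSE)
  }
  storage.mode(data) <- "integer"
  dimnames(data) <- list(NULL, labels)
  structure(data, provenance = as.character(provenance)[1],
            class = c("bgm_dataset", "matrix", "array"))
}

#' @export
print.bgm_dataset <- function(x, ...) {
  cat("Binary dataset: ", nrow(x), " observations of ", ncol(x),
      " variables\n", "provenance: ", attr(x, "provenance"), "\n", sep = "")
  print(head(unclass(x), 5L), ...)
  if (nrow(x) > 5L) cat("... (", nrow(x) - 5L, " more rows)\n", sep = "")
  invisible(x)
}

#' Full conditional probability of one variable
#'
#' Probability that variable `i` equals 1 given the current state of all
#' other variables, under the log-potential parameterization:
#' `logit P(x_i = 1 | x_-i) = h_i + sum_{j != i} J_ij x_j`.
#'
#' @param pot a `bgm_potentials` object from [log_potentials()].
#' @param state length-p 0/1 vector.
#' @param i node index in `1..p`.
#' @return a probability strictly inside (0, 1).
#' @export
conditional_probability <- function(pot, state, i) {
  stopifnot(inherits(pot, "bgm_potentials"))
  p <- length(pot$h)
  if (length(state) != p || !all(state %in% c(0, 1))) {
    stop("`state` must be a length-", p, " 0/1 vector", call. = FALSE)
  }
  if (!(i >= 1 && i <= p)) stop("node index out of range", call. = FALSE)
  # J has zero diagonal so the full inner product excludes state[i] itself
  plogis(pot$h[[i]] + sum(pot$J[i, ] * state))
}

#' Gibbs sampling from an odds-ratio-parameterized binary joint
#'
#' Runs a single Markov chain of full sequential sweeps (each sweep updates
#' variables `1..p` in order from their full conditionals), starting from a
#' state drawn independently from the baseline odds `diag(M)`. The first
#' `burn_in` sweeps are discarded; afterwards one observation is recorded
#' every `spacing` sweeps until `n` rows are collected. With the default
#' spacing the recorded rows are near-independent draws from the joint.
#'
#' @param M an [interaction_matrix()].
#' @param n number of observations to record.
#' @param burn_in number of discarded initial sweeps (default 5000).
#' @param spacing number of sweeps between recorded observations
#'   (default 10).
#' @param seed integer seed; identical seeds give bit-identical output.
#'   `NULL` uses (and advances) the current RNG state.
#' @return a [binary_dataset()] with the generator settings recorded in its
#'   provenance.
#' @examples
#' d <- gibbs_sample(preset_structure("m6"), n = 100, burn_in = 50, seed = 1)
#' colMeans(d)
#' @export
gibbs_sample <- function(M, n, burn_in = 5000, spacing = 10, seed = NULL) {
  M <- as_interaction(M)
  stopifnot(n >= 1, burn_in >= 0, spacing >= 1)
  pot <- log_potentials(M)
  h <- unname(pot$h)
  J <- unname(pot$J)
  p <- length(h)
  out <- matrix(0L, n, p)
  with_seed(seed, {
    x <- as.numeric(runif(p) < plogis(h))
    for (k in seq_len(burn_in)) {
      u <- runif(p)
      for (i in seq_len(p)) {
        eta <- h[i] + sum(J[i, ] * x)
        x[i] <- if (u[i] < 1 / (1 + exp(-eta))) 1 else 0
      }
    }
    for (r in seq_len(n)) {
      for (k in seq_len(spacing)) {
        u <- runif(p)
        for (i in seq_len(p)) {
          eta <- h[i] + sum(J[i, ] * x)
          x[i] <- if (u[i] < 1 / (1 + exp(-eta))) 1 else 0
        }
      }
      out[r, ] <- as.integer(x)
    }
  })
  binary_dataset(
    out, rownames(M),
    provenance = sprintf(
      "gibbs_sample(p = %d, n = %d, burn_in = %d, spacing = %d, seed = %s)",
      p, n, burn_in, spacing, if (is.null(seed)) "NULL" else format(seed)
    )
  )
}

#' Exact joint distribution by enumeration
#'
#' Enumerates all `2^p` binary states and returns their exact probabilities
#' under `P(x) proportional to exp(sum h_i x_i + sum_{i<j} J_ij x_i x_j)`.
#' This is the brute-force oracle against which the Gibbs sampler and the
#' conditional formula are validated; it is limited to `p <= 20`.
#'
#' @inheritParams gibbs_sample
#' @return an object of class `bgm_joint`: list with `states` (2^p x p 0/1
#'   matrix, column names = variable labels) and `prob` (vector summing
#'   to 1).
#' @export
exact_joint <- function(M) {
  M <- as_interaction(M)
  p <- nrow(M)
  if (p > 20L) {
    stop("exact enumeration supports at most 20 variables (got ", p, ")",
         call. = FALSE)
  }
  pot <- log_potentials(M)
  states <- as.matrix(expand.grid(rep(list(0:1), p), KEEP.OUT.ATTRS = FALSE))
  colnames(states) <- rownames(M)
  # x'Jx double-counts each pair, hence the factor 1/2 (diag(J) = 0)
  logw <- states %*% unname(pot$h) +
    rowSums((states %*% unname(pot$J)) * states) / 2
  logw <- logw - max(logw)
  prob <- exp(logw) / sum(exp(logw))
  structure(list(states = states, prob = as.numeric(prob)),
            class = "bgm_joint")
}

#' @export
print.bgm_joint <- function(x, ...) {
  cat("Exact joint over", ncol(x$states), "binary variables (",
      length(x$prob), "states)\n")
  invisible(x)
}
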