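#' Odds-ratio interaction matrix for a pairwise binary Markov random field
#'
#' An interaction matrix `M` is a symmetric p x p matrix of strictly positive
#' reals that parameterizes a joint distribution over p binary variables.
#' The diagonal entry `M[i,i]` is the baseline odds of variable i (its odds
#' of being 1 when all its neighbors are 0); the off-diagonal entry `M[i,j]`
#' is the conditional odds ratio between variables i and j given the rest.
#' An entry of 1 means no interaction: `M[i,j] == 1` encodes conditional
#' independence of i and j, so the support of `M - 1` off the diagonal is
#' the true graph (see [true_graph()]).
#'
#' @param values numeric p x p matrix, symmetric, all entries > 0.
#' @param labels character vector of p unique variable names. Defaults to
#'   the column names of `values`, or `V1..Vp` when absent.
#' @return an object of class `bgm_interaction` (a classed numeric matrix
#'   with dimnames set to the labels).
#' @examples
#' M <- interaction_matrix(matrix(c(1, 2, 2, 1), 2, 2), c("a", "b"))
#' log_potentials(M)
#' @export
interaction_matrix <- function(values, labels = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  p <- nrow(values)
  if (p < 2L || ncol(values) != p) {
    stop("interaction matrix must be square with p >= 2", call. = FALSE)
  }
  bad <- which(!(values > 0), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "interaction matrix entries must be strictly positive; offending cell (%d, %d) = %s",
      bad[1, 1], bad[1, 2], format(values[bad[1, 1], bad[1, 2]])
    ), call. = FALSE)
  }
  if (!isTRUE(all.equal(values, t(values), tolerance = 0))) {
    stop("interaction matrix must be exactly symmetric", call. = FALSE)
  }
  labels <- labels %||% colnames(values) %||% paste0("V", seq_len(p))
  if (length(labels) != p || anyDuplicated(labels) || any(is.na(labels))) {
    stop("`labels` must be ", p, " unique non-missing names", call. = FALSE)
  }
  dimnames(values) <- list(labels, labels)
  structure(values, class = c("bgm_interaction", "matrix", "array"))
}

#' @export
print.bgm_interaction <- function(x, ...) {
  cat("Odds-ratio interaction matrix (", nrow(x), " variables, ",
      nrow(true_graph(x)$edges), " interactions)\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

#' Log-scale potentials of an interaction matrix
#'
#' Converts the odds-ratio parameterization to canonical log-linear
#' potentials: `h[i] = log M[i,i]` (field) and `J[i,j] = log M[i,j]` for
#' `i != j` (pairwise coupling), with `diag(J) = 0`. The implied joint is
#' `P(x) proportional to exp(sum h_i x_i + sum_{i<j} J_ij x_i x_j)`, whose
#' full conditionals are the local logistic regressions
#' `logit P(x_i = 1 | rest) = h_i + sum_{j != i} J_ij x_j`.
#'
#' @param M an [interaction_matrix()].
#' @return an object of class `bgm_potentials`: list with elements `h`
#'   (length-p named vector) and `J` (p x p symmetric matrix, zero diagonal).
#' @export
log_potentials <- function(M) {
  M <- as_interaction(M)
  J <- log(unclass(M))
  h <- diag(J)
  diag(J) <- 0
  structure(list(h = setNames(h, rownames(M)), J = J),
            class = "bgm_potentials")
}

# Accept either a validated object or a plain symmetric matrix.
as_interaction <- function(M) {
  if (inherits(M, "bgm_interaction")) M else interaction_matrix(M)
}

#' True conditional-independence graph of an interaction matrix
#'
#' An edge joins i and j exactly when the pairwise odds ratio differs
#' from 1 (tested as `|M[i,j] - 1| > 1e-9` to tolerate file round-trips).
#'
#' @inheritParams log_potentials
#' @return a [bgm_graph()] over the variable labels of `M`.
#' @export
true_graph <- function(M) {
  M <- as_interaction(M)
  labs <- rownames(M)
  idx <- which(upper.tri(M) & abs(M - 1) > 1e-9, arr.ind = TRUE)
  edges <- cbind(labs[idx[, 1]], labs[idx[, 2]])
  bgm_graph(labs, edges)
}

#' Predefined simulation structures
#'
#' Two fixed interaction matrices used throughout the package's simulation
#' study:
#' \describe{
#'   \item{`"m6"`}{the 6-variable model: baseline odds 1 everywhere, odds
#'     ratio 2 on the four edges (1,2), (1,3), (2,4), (3,4) — a 4-cycle —
#'     with variables 5 and 6 isolated noise.}
#'   \item{`"paper19"`}{a 20-variable structure mimicking a subgraph found
#'     in clinical functioning data: 18 connected nodes carrying exactly 19
#'     edges (two 4-cycles bridged by chains and short branches), plus 2
#'     isolated noise variables. All present edges have odds ratio 2 and
#'     all baseline odds are 1, so an empty estimate has SHD 19 against it.
#'     The edge list is fixed (see source / vignette) so that every study
#'     run refers to the same truth.}
#' }
#'
#' @param name `"m6"` or `"paper19"`.
#' @return an [interaction_matrix()].
#' @examples
#' true_graph(preset_structure("m6"))
#' @export
preset_structure <- function(name) {
  presets <- c("m6", "paper19")
  if (!is.character(name) || length(name) != 1L || !name %in% presets) {
    stop("unknown preset; available presets: ",
         paste(dQuote(presets, FALSE), collapse = ", "), call. = FALSE)
  }
  if (name == "m6") {
    v <- matrix(c(
      1, 2, 2, 1, 1, 1,
      2, 1, 1, 2, 1, 1,
      2, 1, 1, 2, 1, 1,
      1, 2, 2, 1, 1, 1,
      1, 1, 1, 1, 1, 1,
      1, 1, 1, 1, 1, 1
    ), nrow = 6, byrow = TRUE)
    return(interaction_matrix(v, paste0("V", 1:6)))
  }
  # paper19: frozen 19-edge structure on V1..V18; V19, V20 isolated.
  e <- paper19_edges()
  v <- matrix(1, 20, 20)
  for (k in seq_len(nrow(e))) {
    v[e[k, 1], e[k, 2]] <- 2
    v[e[k, 2], e[k, 1]] <- 2
  }
  interaction_matrix(v, paste0("V", 1:20))
}

# Fixed edge list of the "paper19" preset (node indices).
paper19_edges <- function() {
  matrix(c(
    1, 2,   1, 3,   2, 4,   3, 4,    # 4-cycle, as in m6
    4, 5,   5, 6,   6, 7,   7, 8,
    5, 9,   9, 10,  10, 11, 8, 11,   # second cycle closed at 11
    11, 12, 12, 13, 13, 14,
    12, 15, 15, 16, 16, 17, 17, 18
  ), ncol = 2, byrow = TRUE)
}

#' Read / write an interaction matrix as CSV
#'
#' The CSV carries variable names in the first row and first column and a
#' numeric body. On read, symmetry is enforced: discrepancies up to 1e-9
#' are silently symmetrized by averaging (with a warning when the matrix is
#' not exactly symmetric); larger ones are an error.
#'
#' @param path file path.
#' @return `read_interaction_matrix()` returns an [interaction_matrix()];
#'   `write_interaction_matrix()` invisibly returns `path`.
#' @export
read_interaction_matrix <- function(path) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  v <- as.matrix(df)
  if (nrow(v) != ncol(v)) {
    stop("interaction matrix file must be square", call. = FALSE)
  }
  if (!identical(rownames(v), colnames(v))) {
    stop("row and column labels disagree", call. = FALSE)
  }
  if (!is.numeric(v) || anyNA(v)) {
    stop("interaction matrix body must be numeric with no missing values",
         call. = FALSE)
  }
  asym <- max(abs(v - t(v)))
  if (asym > 1e-9) {
    stop("matrix asymmetric beyond tolerance 1e-9 (max |M - t(M)| = ",
         format(asym), ")", call. = FALSE)
  }
  if (asym > 0) {
    warning("matrix not exactly symmetric; symmetrized by averaging")
    v <- (v + t(v)) / 2
  }
  interaction_matrix(v, colnames(v))
}

#' @param M an [interaction_matrix()].
#' @rdname read_interaction_matrix
#' @export
write_interaction_matrix <- function(M, path) {
  M <- as_interaction(M)
  df <- as.data.frame(unclass(M))
  write.csv(df, path, row.names = TRUE, quote = FALSE)
  invisible(path)
}
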