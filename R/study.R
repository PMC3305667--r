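#' Configuration for a simulation study
#'
#' Describes a full grid sweep: the true structure, sample sizes, Bolasso
#' parameters (bootstrap counts, inclusion thresholds, target neighborhood
#' sizes), the estimation methods and edge rules to evaluate, and the
#' replication count. Defaults reproduce the package's reference study
#' grid: n in {50, 100, 200, 500, 1000}, B in {40, 80, 120, 160, 200},
#' pi_cut in {0.90, 0.95, 0.99, 1.00}, and a reduced neighborhood-size grid
#' {1, 2, 5, 10, 18} (the full range on the 20-node preset is 1..18).
#'
#' @param structure preset name (`"m6"`, `"paper19"`) or path to an
#'   interaction-matrix CSV.
#' @param n_grid sample sizes.
#' @param B_grid bootstrap counts (Bolasso methods).
#' @param pi_cut_grid inclusion thresholds in (0, 1] (Bolasso methods).
#' @param l_grid target neighborhood sizes (Bolasso with fixed-size
#'   penalty); values `>= p` are skipped at run time.
#' @param methods subset of `lasso-cv`, `lasso-aic`, `lasso-bic`,
#'   `bolasso`, `bolasso-cv`.
#' @param rules subset of `"OR"`, `"AND"`.
#' @param replicates independent datasets per cell (default 10).
#' @param base_seed integer; every dataset seed is derived from it.
#' @return an object of class `bgm_study_config` (a validated list).
#' @export
study_config <- function(structure = "paper19",
                         n_grid = c(50, 100, 200, 500, 1000),
                         B_grid = c(40, 80, 120, 160, 200),
                         pi_cut_grid = c(0.90, 0.95, 0.99, 1.00),
                         l_grid = c(1, 2, 5, 10, 18),
                         methods = c("lasso-cv", "lasso-aic", "lasso-bic",
                                     "bolasso", "bolasso-cv"),
                         rules = c("OR", "AND"),
                         replicates = 10,
                         base_seed = 1) {
  methods <- match.arg(methods, c("lasso-cv", "lasso-aic", "lasso-bic",
                                  "bolasso", "bolasso-cv"),
                       several.ok = TRUE)
  rules <- match.arg(toupper(rules), c("OR", "AND"), several.ok = TRUE)
  stopifnot(
    length(n_grid) > 0, all(n_grid >= 1),
    length(B_grid) > 0, all(B_grid >= 1),
    length(pi_cut_grid) > 0, all(pi_cut_grid > 0), all(pi_cut_grid <= 1),
    length(l_grid) > 0, all(l_grid >= 1),
    length(replicates) == 1, replicates >= 1,
    is.numeric(base_seed), length(base_seed) == 1
  )
  structure(
    list(structure = structure, n_grid = as.integer(n_grid),
         B_grid = as.integer(B_grid), pi_cut_grid = as.numeric(pi_cut_grid),
         l_grid = as.integer(l_grid), methods = methods, rules = rules,
         replicates = as.integer(replicates),
         base_seed = as.integer(base_seed)),
    class = "bgm_study_config"
  )
}

resolve_structure <- function(structure) {
  if (inherits(structure, "bgm_interaction")) return(structure)
  if (structure %in% c("m6", "paper19")) return(preset_structure(structure))
  if (file.exists(structure)) return(read_interaction_matrix(structure))
  stop("unknown structure: ", structure,
       " (not a preset and not an existing file)", call. = FALSE)
}

# Deterministic per-dataset seed; kept inside 32-bit integer range.
dataset_seed <- function(base_seed, replicate, n) {
  s <- (as.double(base_seed) + 100003 * replicate + n) %% 2147483647
  as.integer(max(s, 1))
}

#' Run a simulation study
#'
#' For every replicate and sample size, draws one Gibbs-sampled dataset
#' from the configured structure and evaluates every configured method on
#' it against the true graph. Bolasso selection indicators are computed
#' once per (replicate, n, l) at the largest configured bootstrap count;
#' smaller `B` values reuse the leading resamples, and all `pi_cut`
#' thresholds are applied post hoc to the same frequencies, without
#' refitting. Both edge rules are evaluated from the same neighborhoods.
#' The whole run is reproducible from `base_seed`.
#'
#' @param config a [study_config()].
#' @param verbose print progress messages.
#' @return a long data.frame of class `bgm_study_result`, one row per
#'   (method, rule, n, B, pi_cut, l, replicate) with columns `shd`,
#'   `sensitivity`, `specificity`, `youden`, and `seed`. Parameters not
#'   applicable to a method are `NA`.
#' @export
run_study <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "bgm_study_config"))
  M <- resolve_structure(config$structure)
  truth <- true_graph(M)
  nodes <- truth$nodes
  p <- length(nodes)
  l_ok <- config$l_grid[config$l_grid <= p - 1]
  if (length(l_ok) < length(config$l_grid)) {
    message("skipping infeasible neighborhood size(s) >= p: ",
            paste(setdiff(config$l_grid, l_ok), collapse = ", "))
  }
  single <- intersect(config$methods, c("lasso-cv", "lasso-aic", "lasso-bic"))
  Bmax <- max(config$B_grid)
  rows <- list()
  add_row <- function(method, rule, n, B, pi_cut, l, rep, seed, res) {
    rows[[length(rows) + 1L]] <<- data.frame(
      method = method, rule = rule, n = n, B = B, pi_cut = pi_cut, l = l,
      replicate = rep, seed = seed, shd = res$shd,
      sensitivity = res$sensitivity, specificity = res$specificity,
      youden = res$youden, tp = res$tp, fp = res$fp, tn = res$tn,
      fn = res$fn, stringsAsFactors = FALSE
    )
  }
  for (rep in seq_len(config$replicates)) {
    for (n in config$n_grid) {
      ds_seed <- dataset_seed(config$base_seed, rep, n)
      data <- gibbs_sample(M, n, seed = ds_seed)
      if (verbose) {
        message(sprintf("replicate %d, n = %d (seed %d)", rep, n, ds_seed))
      }
      for (m in single) {
        nbhd <- lasso_neighborhoods(data, sub("lasso-", "", m),
                                    seed = ds_seed + 1L)
        for (rule in config$rules) {
          res <- evaluate_graph(combine_edges(nbhd, rule), truth)
          add_row(m, rule, n, NA, NA, NA, rep, ds_seed, res)
        }
      }
      if ("bolasso" %in% config$methods && length(l_ok) > 0L) {
        sel <- bolasso_selections_size(data, Bmax, l_ok,
                                       seed = ds_seed + 17L)
        for (k in seq_along(l_ok)) {
          for (Bv in config$B_grid) {
            mu <- colMeans(sel[seq_len(Bv), , , k, drop = FALSE],
                           dims = 1)[, , 1]
            dimnames(mu) <- list(nodes, nodes)
            for (pc in config$pi_cut_grid) {
              nb <- new_neighborhoods(
                nodes, threshold_frequencies(mu, pc), rep(NA_real_, p),
                method = "bolasso", params = list(),
                frequencies = mu, pi_cut = pc, B = Bv
              )
              for (rule in config$rules) {
                res <- evaluate_graph(combine_edges(nb, rule), truth)
                add_row("bolasso", rule, n, Bv, pc, l_ok[k], rep, ds_seed,
                        res)
              }
            }
          }
        }
      }
      if ("bolasso-cv" %in% config$methods) {
        lam_cv <- node_lambdas(data, "cv", folds = 10, seed = ds_seed + 29L)
        sel <- bolasso_selections(data, Bmax, matrix(lam_cv, ncol = 1),
                                  seed = ds_seed + 17L)
        for (Bv in config$B_grid) {
          mu <- colMeans(sel[seq_len(Bv), , , 1, drop = FALSE],
                         dims = 1)[, , 1]
          dimnames(mu) <- list(nodes, nodes)
          for (pc in config$pi_cut_grid) {
            nb <- new_neighborhoods(
              nodes, threshold_frequencies(mu, pc), lam_cv,
              method = "bolasso-cv", params = list(),
              frequencies = mu, pi_cut = pc, B = Bv
            )
            for (rule in config$rules) {
              res <- evaluate_graph(combine_edges(nb, rule), truth)
              add_row("bolasso-cv", rule, n, Bv, pc, NA, rep, ds_seed, res)
            }
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("bgm_study_result", "data.frame")
  out
}

#' Summarize a study result
#'
#' Per estimation cell (method, rule, n, B, pi_cut, l): mean, median,
#' standard deviation, minimum and maximum of SHD and Youden index over
#' replicates. The standard deviation of a single-replicate cell is `NA`.
#'
#' @param results a data.frame from [run_study()].
#' @return a data.frame with one row per distinct cell.
#' @export
summarize_study <- function(results) {
  stopifnot(is.data.frame(results), nrow(results) > 0)
  group_cols <- c("method", "rule", "n", "B", "pi_cut", "l")
  key <- do.call(paste, c(lapply(results[group_cols], addNA_chr), sep = "|"))
  groups <- split(seq_len(nrow(results)), key)
  out <- lapply(groups, function(idx) {
    g <- results[idx, , drop = FALSE]
    cbind(
      g[1, group_cols, drop = FALSE],
      data.frame(
        replicates = nrow(g),
        shd_mean = mean(g$shd), shd_median = median(g$shd),
        shd_sd = if (nrow(g) > 1) sd(g$shd) else NA_real_,
        shd_min = min(g$shd), shd_max = max(g$shd),
        youden_mean = mean(g$youden), youden_median = median(g$youden),
        youden_sd = if (nrow(g) > 1) sd(g$youden) else NA_real_,
        youden_min = min(g$youden), youden_max = max(g$youden)
      )
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$method, out$rule, out$n, out$B, out$pi_cut, out$l), ]
}

addNA_chr <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- "<NA>"
  x
}

#' Optimal Bolasso configuration from study results
#'
#' Regresses the chosen outcome on factor-coded `pi_cut`, `B` and `l`
#' plus the `pi_cut:l` interaction over the fixed-size Bolasso rows
#' (ordinary least squares), and returns the grid cell whose fitted value
#' is minimal (SHD) or maximal (Youden index). The raw cell-mean
#' argmin/argmax is reported alongside as a robustness check.
#'
#' @param results a data.frame from [run_study()] containing `bolasso`
#'   rows with at least two levels of each of `pi_cut`, `B`, `l`.
#' @param outcome `"shd"` (minimized) or `"youden"` (maximized).
#' @return list with elements `by_model` and `by_cell_mean`, each a list
#'   with `pi_cut`, `B`, `l` and the corresponding fitted/observed value,
#'   plus the fitted `model`.
#' @export
optimal_configuration <- function(results, outcome = c("shd", "youden")) {
  outcome <- match.arg(outcome)
  rows <- results[results$method == "bolasso" &
                    !is.na(results$pi_cut) & !is.na(results$B) &
                    !is.na(results$l), , drop = FALSE]
  if (nrow(rows) == 0L) stop("no bolasso rows in results", call. = FALSE)
  for (f in c("pi_cut", "B", "l")) {
    if (length(unique(rows[[f]])) < 2L) {
      stop("factor `", f, "` needs at least 2 levels (has ",
           length(unique(rows[[f]])), ")", call. = FALSE)
    }
  }
  rows$f_pi <- factor(rows$pi_cut)
  rows$f_B <- factor(rows$B)
  rows$f_l <- factor(rows$l)
  fml <- as.formula(paste(outcome, "~ f_pi + f_B + f_l + f_pi:f_l"))
  fit <- lm(fml, data = rows)
  cells <- unique(rows[, c("f_pi", "f_B", "f_l")])
  fitted_vals <- predict(fit, newdata = cells)
  pick_fit <- if (outcome == "shd") which.min(fitted_vals) else which.max(fitted_vals)
  cell_means <- aggregate(rows[[outcome]],
                          by = list(pi_cut = rows$pi_cut, B = rows$B,
                                    l = rows$l), FUN = mean)
  pick_raw <- if (outcome == "shd") which.min(cell_means$x) else which.max(cell_means$x)
  list(
    outcome = outcome,
    by_model = list(
      pi_cut = as.numeric(as.character(cells$f_pi[pick_fit])),
      B = as.integer(as.character(cells$f_B[pick_fit])),
      l = as.integer(as.character(cells$f_l[pick_fit])),
      fitted = unname(fitted_vals[pick_fit])
    ),
    by_cell_mean = list(
      pi_cut = cell_means$pi_cut[pick_raw],
      B = cell_means$B[pick_raw],
      l = cell_means$l[pick_raw],
      mean = cell_means$x[pick_raw]
    ),
    model = fit
  )
}
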