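#' Confusion counts between an estimated and a true graph
#'
#' Classifies every unordered node pair: a true positive is an edge present
#' in both graphs, a false positive an edge only in the estimate, a false
#' negative an edge only in the truth, and a true negative a pair absent
#' from both. The four counts always sum to `p(p-1)/2`.
#'
#' @param est,truth [bgm_graph()] objects over the same node set (order
#'   does not matter).
#' @return an object of class `bgm_confusion`: list with integer fields
#'   `tp`, `fp`, `tn`, `fn` and the number of nodes `p`.
#' @export
confusion <- function(est, truth) {
  stopifnot(inherits(est, "bgm_graph"), inherits(truth, "bgm_graph"))
  if (!setequal(est$nodes, truth$nodes)) {
    stop("node sets differ; only in estimate: {",
         paste(setdiff(est$nodes, truth$nodes), collapse = ", "),
         "}, only in truth: {",
         paste(setdiff(truth$nodes, est$nodes), collapse = ", "), "}",
         call. = FALSE)
  }
  p <- length(truth$nodes)
  e <- graph_keys(est)
  t_ <- graph_keys(truth)
  tp <- length(intersect(e, t_))
  fp <- length(setdiff(e, t_))
  fn <- length(setdiff(t_, e))
  tn <- p * (p - 1) / 2 - tp - fp - fn
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, p = p),
            class = "bgm_confusion")
}

#' @export
print.bgm_confusion <- function(x, ...) {
  cat(sprintf("Edge confusion over %d pairs: TP %d, FP %d, TN %d, FN %d\n",
              x$p * (x$p - 1) / 2, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Structural Hamming Distance
#'
#' Number of edge insertions or deletions needed to transform one
#' undirected graph into the other: the size of the symmetric difference
#' of the edge sets, identically equal to FP + FN.
#'
#' @inheritParams confusion
#' @return non-negative integer.
#' @export
shd <- function(est, truth) {
  cc <- confusion(est, truth)
  cc$fp + cc$fn
}

#' Performance metrics from edge confusion counts
#'
#' Sensitivity `q = TP / (TP + FN)`, specificity `p = TN / (TN + FP)`, and
#' the Youden index `J = q + p - 1`, all over the set of unordered node
#' pairs, plus the Structural Hamming Distance `FP + FN`. Degenerate
#' denominators follow the vacuous-truth convention: `q = 1` when the true
#' graph has no edges and `p = 1` when it is complete, so `J` is always
#' defined.
#'
#' @param counts a `bgm_confusion` from [confusion()].
#' @return an object of class `bgm_metrics`: list with `shd`,
#'   `sensitivity`, `specificity`, `youden`.
#' @export
performance_metrics <- function(counts) {
  stopifnot(inherits(counts, "bgm_confusion"))
  q <- if (counts$tp + counts$fn == 0) 1 else counts$tp / (counts$tp + counts$fn)
  p_spec <- if (counts$tn + counts$fp == 0) 1 else counts$tn / (counts$tn + counts$fp)
  structure(
    list(shd = counts$fp + counts$fn, sensitivity = q,
         specificity = p_spec, youden = q + p_spec - 1),
    class = "bgm_metrics"
  )
}

#' @export
print.bgm_metrics <- function(x, ...) {
  cat(sprintf("SHD %d | sensitivity %.4f | specificity %.4f | Youden J %.4f\n",
              x$shd, x$sensitivity, x$specificity, x$youden))
  invisible(x)
}

#' Score an estimated graph against a known truth
#'
#' Convenience wrapper returning confusion counts and all performance
#' metrics in one flat list.
#'
#' @inheritParams confusion
#' @return list with `tp`, `fp`, `tn`, `fn`, `shd`, `sensitivity`,
#'   `specificity`, `youden`.
#' @examples
#' truth <- true_graph(preset_structure("m6"))
#' empty <- bgm_graph(truth$nodes)
#' evaluate_graph(empty, truth)
#' @export
evaluate_graph <- function(est, truth) {
  cc <- confusion(est, truth)
  m <- performance_metrics(cc)
  list(tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn, shd = m$shd,
       sensitivity = m$sensitivity, specificity = m$specificity,
       youden = m$youden)
}
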