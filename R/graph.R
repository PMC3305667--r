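#' Undirected labeled graph
#'
#' Lightweight container for the true and estimated structures: a node
#' label set plus an edge set of unordered label pairs. Edges are stored in
#' canonical form (lexicographically smaller label first, rows sorted,
#' duplicates removed); self-loops are rejected.
#'
#' @param nodes character vector of unique node labels.
#' @param edges two-column character matrix (or empty) of edges; endpoints
#'   must be in `nodes`.
#' @param method,rule,params optional estimation metadata recorded on
#'   estimated graphs.
#' @param frequencies optional named numeric vector of per-edge bootstrap
#'   selection frequencies (names are canonical edge keys).
#' @return an object of class `bgm_graph`: list with elements `nodes`,
#'   `edges` (m x 2 character matrix), and optional metadata fields.
#' @examples
#' g <- bgm_graph(c("a", "b", "c"), rbind(c("b", "a")))
#' g$edges
#' @export
bgm_graph <- function(nodes, edges = NULL, method = NULL, rule = NULL,
                      params = NULL, frequencies = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node labels", call. = FALSE)
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(character(0), 0, 2)
  } else {
    edges <- matrix(as.character(edges), ncol = 2)
  }
  if (any(edges[, 1] == edges[, 2])) {
    stop("self-loops are not allowed", call. = FALSE)
  }
  missing_nodes <- setdiff(c(edges), nodes)
  if (length(missing_nodes) > 0L) {
    stop("edge endpoints not in node set: ",
         paste(missing_nodes, collapse = ", "), call. = FALSE)
  }
  edges <- canonical_edges(edges)
  structure(
    list(nodes = nodes, edges = edges, method = method, rule = rule,
         params = params, frequencies = frequencies),
    class = "bgm_graph"
  )
}

canonical_edges <- function(edges) {
  if (nrow(edges) == 0L) return(matrix(character(0), 0, 2))
  a <- pmin(edges[, 1], edges[, 2])
  b <- pmax(edges[, 1], edges[, 2])
  e <- unique(cbind(a, b))
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  dimnames(e) <- NULL
  e
}

#' @export
print.bgm_graph <- function(x, ...) {
  cat("Undirected graph: ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges\n", sep = "")
  if (!is.null(x$method)) {
    cat("method: ", x$method, " (", x$rule, "-rule)\n", sep = "")
  }
  if (nrow(x$edges) > 0L) {
    shown <- head(x$edges, 10L)
    cat(paste0("  ", shown[, 1], " -- ", shown[, 2], collapse = "\n"), "\n")
    if (nrow(x$edges) > 10L) {
      cat("  ... (", nrow(x$edges) - 10L, " more)\n", sep = "")
    }
  }
  invisible(x)
}

graph_keys <- function(g) {
  if (nrow(g$edges) == 0L) character(0) else edge_key(g$edges[, 1], g$edges[, 2])
}

#' Write a graph to disk
#'
#' `format = "edgelist"` writes a headerless two-column TSV of canonical
#' edge pairs plus a sidecar file `<path>.nodes` listing every node (one
#' per line) so that isolated nodes survive the round trip.
#' `format = "graphml"` writes standard GraphML (via igraph) with node
#' labels and, when available, a numeric `frequency` edge attribute holding
#' the Bolasso selection frequency.
#'
#' @param g a [bgm_graph()].
#' @param path output file path.
#' @param format `"edgelist"` or `"graphml"`.
#' @return invisibly, `path`.
#' @export
write_graph_file <- function(g, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(g, "bgm_graph"))
  if (format == "edgelist") {
    con <- file(path, "w")
    on.exit(close(con))
    if (nrow(g$edges) > 0L) {
      writeLines(paste(g$edges[, 1], g$edges[, 2], sep = "\t"), con)
    }
    writeLines(g$nodes, paste0(path, ".nodes"))
  } else {
    ig <- igraph::make_empty_graph(n = length(g$nodes), directed = FALSE)
    ig <- igraph::set_vertex_attr(ig, "name", value = g$nodes)
    if (nrow(g$edges) > 0L) {
      ig <- igraph::add_edges(ig, t(g$edges))
      if (!is.null(g$frequencies)) {
        keys <- graph_keys(g)
        ig <- igraph::set_edge_attr(ig, "frequency",
                                    value = unname(g$frequencies[keys]))
      }
    }
    igraph::write_graph(ig, path, format = "graphml")
  }
  invisible(path)
}

#' Read a graph from an edge-list TSV
#'
#' Reads a two-column tab-separated edge list (as written by
#' [write_graph_file()]). The node set is taken from the sidecar
#' `<path>.nodes` file when present, from `nodes` when given, and from the
#' union of edge endpoints otherwise.
#'
#' @param path edge-list file path.
#' @param nodes optional explicit node label vector.
#' @return a [bgm_graph()].
#' @export
read_graph_file <- function(path, nodes = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  edges <- if (length(lines) > 0L) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) != 2L)) {
      stop("malformed edge list: each line must be 'nodeA<TAB>nodeB'",
           call. = FALSE)
    }
    do.call(rbind, parts)
  } else {
    NULL
  }
  sidecar <- paste0(path, ".nodes")
  if (is.null(nodes) && file.exists(sidecar)) {
    nodes <- readLines(sidecar)
    nodes <- nodes[nzchar(nodes)]
  }
  if (is.null(nodes)) nodes <- sort(unique(c(edges)))
  bgm_graph(nodes, edges)
}
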