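#' Interdependency (ID) graph
#'
#' Directed weighted graph over features built from split co-occurrence
#' along decision-tree paths. Within one tree, every internal node `n` and
#' every ancestor node `a` on its path to the root yields a candidate
#' contribution for the edge `feature(a) -> feature(n)`:
#' `wAcc^u * IG(n) * (count(n)/count(root))^v / dist(a, n)`
#' (dist = number of tree edges between them; wAcc the tree's held-out
#' weighted accuracy — the same structure-analysis weighting that drives
#' RI, divided by the path distance). Each ordered feature pair is
#' credited once per tree with its strongest contribution, and the edge
#' count tallies the number of trees in which the pair co-occurs. Edge
#' weight therefore rises with the number of co-occurring trees and falls
#' with path distance, while low-quality trees and tiny deep nodes
#' contribute almost nothing. An edge `g -> g` can only arise from two
#' distinct nodes on one path both splitting on `g`.
#'
#' @param edges data.frame with columns `from`, `to`, `weight`, `count`.
#' @param ri optional named RI vector attached to the nodes.
#' @return an object of class `id_graph`.
#' @export
id_graph <- function(edges = data.frame(from = character(0), to = character(0),
                                        weight = numeric(0), count = integer(0)),
                     ri = NULL) {
  stopifnot(all(c("from", "to", "weight", "count") %in% colnames(edges)))
  if (any(edges$weight < 0)) stop("edge weights must be non-negative")
  structure(list(edges = edges, ri = ri), class = "id_graph")
}

#' @export
print.id_graph <- function(x, ...) {
  nn <- length(unique(c(x$edges$from, x$edges$to)))
  cat("id_graph:", nn, "nodes,", nrow(x$edges), "directed edges\n")
  if (nrow(x$edges)) {
    cat("  strongest edges:\n")
    print(top_edges(x, min(5L, nrow(x$edges))), row.names = FALSE)
  }
  invisible(x)
}

#' Accumulate the ID graph from a tree collection
#'
#' Reference implementation over explicit `mcfs_tree` objects (the
#' streaming C++ path inside [mcfs()] computes the same aggregation).
#' Each ordered feature pair is credited once per tree with its strongest
#' ancestor-descendant contribution; the result is additive over tree
#' collections.
#'
#' @param trees list of `mcfs_tree` objects (e.g. from
#'   [run_projections()]).
#' @param cfg an [mcfs_config()] supplying the `u`, `v` exponents and the
#'   weighting mode.
#' @return an [id_graph()].
#' @export
accumulate_id <- function(trees, cfg = mcfs_config()) {
  ig_weighted <- cfg$id_weighting == "ig"
  acc <- new.env(parent = emptyenv())
  for (tr in trees) {
    internal <- which(!is.na(tr$feature))
    if (!length(internal) || (ig_weighted && is.na(tr$wacc))) next
    wu <- if (ig_weighted) tr$wacc^cfg$u else 1
    tree_best <- list() # strongest contribution per ordered pair, this tree
    for (n in internal) {
      node_w <- wu * tr$ig[n] * (tr$count[n] / tr$count[1])^cfg$v
      a <- tr$parent[n]
      while (!is.na(a)) {
        if (!is.na(tr$feature[a])) {
          key <- paste0(tr$feature_ids[tr$feature[a]], "\r",
                        tr$feature_ids[tr$feature[n]])
          d <- tr$depth[n] - tr$depth[a]
          w <- if (ig_weighted) node_w / d else 1 / d
          if (is.null(tree_best[[key]]) || w > tree_best[[key]])
            tree_best[[key]] <- w
        }
        a <- tr$parent[a]
      }
    }
    for (key in names(tree_best)) {
      prev <- if (is.null(acc[[key]])) c(0, 0) else acc[[key]]
      acc[[key]] <- prev + c(tree_best[[key]], 1)
    }
  }
  keys <- ls(acc)
  if (!length(keys)) return(id_graph())
  parts <- strsplit(keys, "\r", fixed = TRUE)
  edges <- data.frame(
    from = vapply(parts, `[`, "", 1), to = vapply(parts, `[`, "", 2),
    weight = vapply(keys, function(k) acc[[k]][1], 0),
    count = as.integer(vapply(keys, function(k) acc[[k]][2], 0)),
    stringsAsFactors = FALSE, row.names = NULL)
  edges <- edges[order(edges$from, edges$to, method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL
  id_graph(edges)
}

#' Strongest interdependency edges
#'
#' Edges ranked by weight (descending); ties break by co-occurrence count,
#' then lexicographically by endpoints, so the order is deterministic. The
#' default `k = 60` matches the number of interdependencies customarily
#' visualised. Self-loops (a feature re-split along its own path) are kept
#' in the graph but excluded from this ranking by default: an
#' interdependency is a pairwise relation between two distinct features.
#'
#' @param g an [id_graph()].
#' @param k number of edges to return.
#' @param include_self also rank self-loop edges (default FALSE).
#' @return data.frame of the top `k` edges (all edges, with a warning, if
#'   fewer exist).
#' @export
top_edges <- function(g, k = 60L, include_self = FALSE) {
  stopifnot(inherits(g, "id_graph"), k >= 1)
  e <- g$edges
  if (!include_self) e <- e[e$from != e$to, , drop = FALSE]
  if (k > nrow(e)) {
    if (nrow(e) < k) warning("only ", nrow(e), " edge(s) available; returning all")
    k <- nrow(e)
  }
  ord <- order(-e$weight, -e$count, e$from, e$to, method = "radix")
  out <- e[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert an ID graph to igraph / write it out
#'
#' `as_igraph()` returns an [igraph::graph_from_data_frame()] object with
#' RI as a node attribute; `write_id_graph()` writes the edge list as TSV
#' and, optionally, GraphML for external viewers.
#'
#' @param g an [id_graph()].
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "id_graph"))
  verts <- unique(c(g$edges$from, g$edges$to))
  vd <- data.frame(name = verts,
                   ri = if (is.null(g$ri)) NA_real_ else unname(g$ri[verts]))
  igraph::graph_from_data_frame(g$edges, directed = TRUE, vertices = vd)
}

#' @rdname as_igraph
#' @param path TSV output path.
#' @param graphml optional GraphML output path.
#' @export
write_id_graph <- function(g, path, graphml = NULL) {
  utils::write.table(g$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(graphml))
    igraph::write_graph(as_igraph(g), graphml, format = "graphml")
  invisible(path)
}
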