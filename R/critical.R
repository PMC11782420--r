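# Critical-node identification: betweenness centrality combined with
# dominance-frontier membership.

#' Dominance frontiers of a rooted directed graph
#'
#' A node `n` dominates `m` when every path from the source to `m`
#' passes through `n`. The dominance frontier of `n` is the set of nodes
#' `m` such that `n` dominates a predecessor of `m` but does not
#' strictly dominate `m` -- the points where `n`'s dominance ends.
#' Computed from the immediate-dominator tree by the standard
#' predecessor-walk algorithm. Nodes unreachable from the source are
#' excluded with a warning.
#'
#' @param net A `glyco_grn`.
#' @param source Root node id; defaults to `net$source`.
#' @return Named list mapping each reachable node id to a character
#'   vector of frontier node ids.
#' @export
dominance_frontiers <- function(net, source = net$source) {
  stopifnot(inherits(net, "glyco_grn"), !is.null(source))
  g <- net$graph
  reach <- .reachable_from(g, source)
  if (length(reach) < igraph::vcount(g)) {
    warning("excluding ", igraph::vcount(g) - length(reach),
            " node(s) unreachable from source")
    g <- igraph::induced_subgraph(g, reach)
  }
  vn <- igraph::V(g)$name
  dt <- igraph::dominator_tree(g, root = source, mode = "out")
  idom <- dt$dom                     # idom index per vertex (-1/NA at root)
  names(idom) <- vn
  df <- stats::setNames(vector("list", length(vn)), vn)
  df[] <- list(character())
  root_i <- match(source, vn)
  for (m in seq_along(vn)) {
    preds <- as.integer(igraph::neighbors(g, vn[m], mode = "in"))
    if (length(preds) < 1L) next
    for (p in preds) {
      runner <- p
      while (!is.na(runner) && runner != idom[m] && runner > 0) {
        df[[runner]] <- union(df[[runner]], vn[m])
        if (runner == root_i) break
        runner <- idom[runner]
      }
    }
  }
  df
}

#' Dominance-frontier membership counts
#'
#' For each node, the number of dominance-frontier sets it belongs to.
#'
#' @inheritParams dominance_frontiers
#' @return Named integer vector over reachable nodes.
#' @export
df_membership <- function(net, source = net$source) {
  df <- suppressWarnings(dominance_frontiers(net, source))
  all_members <- unlist(df, use.names = FALSE)
  counts <- table(factor(all_members, levels = names(df)))
  stats::setNames(as.integer(counts), names(df))
}

#' Identify critical nodes of a reaction network
#'
#' A node is critical when its betweenness centrality and its
#' dominance-frontier membership both strictly exceed the respective
#' percentile thresholds over all nodes (default: the 50th percentile,
#' i.e. above-median on both metrics). Critical nodes mark convergence
#' hubs of the biosynthetic network and anchor the stages of the
#' sequential parameter-estimation strategy. Critical tags are ordered
#' by breadth-first distance of each tag's nearest node from the source
#' (ties broken lexicographically); all structural isomorphs of a
#' critical tag are retained downstream.
#'
#' @param net A `glyco_grn`.
#' @param source Source node id; defaults to `net$source`.
#' @param betweenness_percentile,df_percentile Percentile thresholds
#'   (0-100) applied with strict inequality (default 50).
#' @return A `critical_node_report`: list with `betweenness` (named
#'   numeric), `df_membership` (named integer), `critical_nodes`
#'   (character), `critical_tags` (ordered character). Empty
#'   `critical_nodes` triggers a warning.
#' @export
identify_critical_nodes <- function(net, source = net$source,
                                    betweenness_percentile = 50,
                                    df_percentile = 50) {
  stopifnot(inherits(net, "glyco_grn"), !is.null(source))
  g <- net$graph
  btw <- igraph::betweenness(g, directed = TRUE, weights = NA)
  dfm <- df_membership(net, source)
  dfm_full <- stats::setNames(integer(igraph::vcount(g)), igraph::V(g)$name)
  dfm_full[names(dfm)] <- dfm
  b_thr <- stats::quantile(btw, betweenness_percentile / 100, names = FALSE)
  d_thr <- stats::quantile(dfm_full, df_percentile / 100, names = FALSE)
  crit <- names(btw)[btw > b_thr & dfm_full > d_thr]
  if (!length(crit))
    warning("no node exceeds both percentile thresholds; ",
            "strategy degrades to a single stage")
  tags <- igraph::V(g)$tag[match(crit, igraph::V(g)$name)]
  ord <- .order_tags_by_distance(net, unique(tags), source)
  structure(list(betweenness = btw,
                 df_membership = dfm_full,
                 critical_nodes = crit,
                 critical_tags = ord),
            class = "critical_node_report")
}

# Order tags by BFS distance of their nearest isomorph from the source;
# ties broken lexicographically.
.order_tags_by_distance <- function(net, tags, source) {
  if (!length(tags)) return(character())
  d <- igraph::distances(net$graph, v = source, mode = "out")[1, ]
  nearest <- vapply(tags, function(tg) {
    min(d[tag_to_nodes(net, tg)])
  }, numeric(1))
  tags[order(nearest, tags)]
}

#' @export
print.critical_node_report <- function(x, ...) {
  cat("<critical_node_report>\n",
      "  critical tags: ", paste(x$critical_tags, collapse = " -> "), "\n",
      "  critical nodes: ", paste(x$critical_nodes, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}
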