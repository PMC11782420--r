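# Pairwise comparison of reaction networks: overlap, isomorphism,
# graph edit distance, subgraph containment.

#' Compare two reaction networks
#'
#' Node identity is given by the LinearCode string; edge identity by the
#' (substrate, product, enzyme) LinearCode triple. Isomorphism and
#' subgraph containment are tested with attribute matching (VF2 with
#' LinearCode vertex colours and enzyme edge colours). Graph edit
#' distance uses unit insertion/deletion costs for nodes and edges and
#' substitution cost 0 iff the LinearCode matches (else 1); it is exact
#' for small graphs and otherwise an anytime upper bound, flagged as
#' such. The normalised GED divides by the mean edge count of the pair.
#'
#' @param g1,g2 `glyco_grn` networks.
#' @param ged_timeout Seconds allowed for the exact GED search before
#'   falling back to the upper bound (default 10).
#' @param ged_exact_max Largest node count for which exact GED is
#'   attempted (default 12).
#' @return A `graph_comparison` list: `node_overlap`, `edge_overlap`,
#'   `isomorphic`, `ged`, `ged_exact` (FALSE when `ged` is an upper
#'   bound), `ged_normalized`, `subgraph_1_of_2`, `subgraph_2_of_1`.
#' @export
compare_graphs <- function(g1, g2, ged_timeout = 10, ged_exact_max = 12) {
  stopifnot(inherits(g1, "glyco_grn"), inherits(g2, "glyco_grn"))
  lc1 <- igraph::V(g1$graph)$linear_code
  lc2 <- igraph::V(g2$graph)$linear_code
  e1 <- .edge_keys(g1); e2 <- .edge_keys(g2)
  node_overlap <- length(intersect(lc1, lc2))
  edge_overlap <- length(intersect(e1, e2))

  iso <- .iso_attr(g1$graph, g2$graph)
  ged <- .ged(g1, g2, timeout = ged_timeout, exact_max = ged_exact_max)
  mean_e <- mean(c(length(e1), length(e2)))

  structure(list(
    node_overlap = node_overlap,
    edge_overlap = edge_overlap,
    isomorphic = iso,
    ged = ged$cost,
    ged_exact = ged$exact,
    ged_normalized = if (mean_e > 0) ged$cost / mean_e else NA_real_,
    subgraph_1_of_2 = .subgraph_of(g1, g2),
    subgraph_2_of_1 = .subgraph_of(g2, g1)),
    class = "graph_comparison")
}

#' @export
print.graph_comparison <- function(x, ...) {
  cat("<graph_comparison>\n",
      "  node overlap: ", x$node_overlap,
      "   edge overlap: ", x$edge_overlap, "\n",
      "  isomorphic: ", x$isomorphic, "\n",
      "  GED: ", x$ged, if (!x$ged_exact) " (upper bound)",
      "   normalised: ", round(x$ged_normalized, 3), "\n",
      "  subgraph 1-of-2: ", x$subgraph_1_of_2,
      "   2-of-1: ", x$subgraph_2_of_1, "\n", sep = "")
  invisible(x)
}

.edge_keys <- function(net) {
  e <- network_edges(net)
  if (!nrow(e)) return(character())
  lc <- stats::setNames(igraph::V(net$graph)$linear_code,
                        igraph::V(net$graph)$name)
  paste(lc[e$from], lc[e$to], e$enzyme, sep = " -> ")
}

# VF2 isomorphism with LinearCode vertex colours and enzyme edge colours.
.iso_attr <- function(ga, gb) {
  if (igraph::vcount(ga) != igraph::vcount(gb) ||
      igraph::ecount(ga) != igraph::ecount(gb)) return(FALSE)
  cols <- .shared_colours(ga, gb)
  igraph::is_isomorphic_to(ga, gb, method = "vf2",
                           vertex.color1 = cols$v1, vertex.color2 = cols$v2,
                           edge.color1 = cols$e1, edge.color2 = cols$e2)
}

# Labelled subgraph containment: since node identity is the LinearCode,
# `a` is a subgraph of `b` iff every labelled node and every labelled
# edge of `a` occurs in `b`.
.subgraph_of <- function(a, b) {
  all(igraph::V(a$graph)$linear_code %in% igraph::V(b$graph)$linear_code) &&
    all(.edge_keys(a) %in% .edge_keys(b))
}

.shared_colours <- function(ga, gb) {
  vlev <- unique(c(igraph::V(ga)$linear_code, igraph::V(gb)$linear_code))
  elev <- unique(c(igraph::E(ga)$enzyme, igraph::E(gb)$enzyme, "_"))
  list(v1 = match(igraph::V(ga)$linear_code, vlev),
       v2 = match(igraph::V(gb)$linear_code, vlev),
       e1 = if (igraph::ecount(ga)) match(igraph::E(ga)$enzyme, elev) else integer(),
       e2 = if (igraph::ecount(gb)) match(igraph::E(gb)$enzyme, elev) else integer())
}

# ---- graph edit distance ---------------------------------------------------

# Cost model: node substitution 0 iff LinearCode matches else 1;
# node/edge insertion and deletion 1. Exact branch-and-bound over node
# assignments for small graphs; greedy label assignment as the anytime
# upper bound / fallback.
.ged <- function(g1, g2, timeout, exact_max) {
  lc1 <- igraph::V(g1$graph)$linear_code
  lc2 <- igraph::V(g2$graph)$linear_code
  a1 <- .adj_list(g1); a2 <- .adj_list(g2)
  ub <- .ged_greedy(lc1, lc2, a1, a2)
  n1 <- length(lc1); n2 <- length(lc2)
  if (max(n1, n2) > exact_max)
    return(list(cost = ub, exact = FALSE))
  t0 <- Sys.time()
  best <- new.env(parent = emptyenv())
  best$cost <- ub
  best$timed_out <- FALSE
  .ged_branch(integer(0), lc1, lc2, a1, a2, best, t0, timeout)
  list(cost = best$cost, exact = !best$timed_out)
}

.adj_list <- function(net) {
  e <- network_edges(net)
  lc <- stats::setNames(igraph::V(net$graph)$linear_code,
                        igraph::V(net$graph)$name)
  list(from = lc[e$from], to = lc[e$to], enzyme = e$enzyme, lc = unname(lc))
}

# Edit cost of a complete assignment: map is an integer vector over g1
# nodes (index into g2 nodes, or 0 = deletion); unmapped g2 nodes are
# insertions. Edge costs follow the induced correspondence.
.ged_assignment_cost <- function(map, lc1, lc2, a1, a2) {
  cost <- sum(map == 0L)                                   # node deletions
  cost <- cost + (length(lc2) - sum(map > 0L))             # node insertions
  if (any(map > 0L))
    cost <- cost + sum(lc1[map > 0L] != lc2[map[map > 0L]])  # substitutions
  # edges of g1: kept iff both ends mapped and a matching edge (same
  # enzyme) exists between the images; otherwise deleted
  i1 <- match(a1$from, a1$lc); j1 <- match(a1$to, a1$lc)
  m2key <- paste(a2$from, a2$to, a2$enzyme)
  mapped_edge <- map[i1] > 0L & map[j1] > 0L
  key1 <- paste(lc2[map[i1]], lc2[map[j1]], a1$enzyme)
  kept <- mapped_edge & key1 %in% m2key
  cost <- cost + sum(!kept)                                # edge deletions
  cost + (length(a2$from) - sum(kept))                     # edge insertions
}

.ged_branch <- function(map, lc1, lc2, a1, a2, best, t0, timeout) {
  if (best$timed_out) return()
  if (as.numeric(Sys.time() - t0, units = "secs") > timeout) {
    best$timed_out <- TRUE
    return()
  }
  k <- length(map)
  n1 <- length(lc1); n2 <- length(lc2)
  if (k == n1) {
    cost <- .ged_assignment_cost(map, lc1, lc2, a1, a2)
    if (cost < best$cost) best$cost <- cost
    return()
  }
  # admissible lower bound on node costs of the partial assignment
  lb <- sum(map == 0L) + if (k) sum(lc1[seq_len(k)][map > 0L] !=
                                    lc2[map[map > 0L]]) else 0
  if (lb >= best$cost) return()
  cands <- c(setdiff(seq_len(n2), map[map > 0L]), 0L)
  # try exact-label matches first for tighter early bounds
  cands <- cands[order(!(cands > 0L & lc2[pmax(cands, 1L)] == lc1[k + 1L]))]
  for (j in cands)
    .ged_branch(c(map, j), lc1, lc2, a1, a2, best, t0, timeout)
}

# Greedy upper bound: match identical LinearCodes, delete/insert the rest.
.ged_greedy <- function(lc1, lc2, a1, a2) {
  map <- match(lc1, lc2)
  # resolve duplicate targets: keep first occurrence only
  dup <- duplicated(map, incomparables = NA)
  map[dup] <- NA
  map[is.na(map)] <- 0L
  .ged_assignment_cost(as.integer(map), lc1, lc2, a1, a2)
}
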