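# Brute-force graph oracles and small fixture builders used across the
# test files. The oracles enumerate paths explicitly and stay
# independent of the package's implementations.

# A minimal reaction network from an edge table; node ids double as
# LinearCode strings unless a lookup is supplied.
tiny_net <- function(edges, source = NULL, sinks = character(),
                     linear_code = NULL) {
  ids <- unique(c(edges$from, edges$to))
  lc <- if (is.null(linear_code)) setNames(ids, ids) else linear_code
  nodes <- data.frame(id = ids, linear_code = unname(lc[ids]),
                      tag = ids, stringsAsFactors = FALSE)
  reaction_network(nodes, edges, source = source, sinks = sinks)
}

edge_df <- function(from, to, enzyme = "ManI") {
  data.frame(from = from, to = to,
             enzyme = rep_len(enzyme, length(from)),
             stringsAsFactors = FALSE)
}

# Random connected DAG on n nodes: edges only from lower to higher
# topological index, node 1 as source, guaranteed in-edge per node.
random_dag <- function(n, p = 0.35, seed = 1) {
  set.seed(seed)
  from <- character(0); to <- character(0)
  ids <- sprintf("n%02d", seq_len(n))
  for (j in 2:n) {
    preds <- which(stats::runif(j - 1) < p)
    if (!length(preds)) preds <- sample.int(j - 1, 1)
    from <- c(from, ids[preds]); to <- c(to, rep(ids[j], length(preds)))
  }
  tiny_net(edge_df(from, to), source = ids[1])
}

# All simple directed paths between two nodes by depth-first search.
enumerate_paths <- function(edges, from, to) {
  adj <- split(edges$to, edges$from)
  out <- list()
  walk <- function(node, path) {
    if (node == to) { out[[length(out) + 1L]] <<- path; return() }
    for (nxt in adj[[node]] %||% character())
      if (!nxt %in% path) walk(nxt, c(path, nxt))
  }
  walk(from, from)
  out
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Dominators by definition: d dominates m iff d lies on every
# source->m path.
brute_dominators <- function(net, source) {
  edges <- network_edges(net)
  nodes <- igraph::V(net$graph)$name
  reach <- nodes[vapply(nodes, function(m)
    length(enumerate_paths(edges, source, m)) > 0 || m == source, TRUE)]
  doms <- lapply(reach, function(m) {
    if (m == source) return(source)
    paths <- enumerate_paths(edges, source, m)
    Reduce(intersect, paths)
  })
  setNames(doms, reach)
}

# Dominance frontiers from brute-force dominators and the definition:
# DF(n) = { m : n dominates some predecessor of m, n does not strictly
# dominate m }.
brute_dominance_frontiers <- function(net, source) {
  doms <- brute_dominators(net, source)
  nodes <- names(doms)
  edges <- network_edges(net)
  df <- setNames(lapply(nodes, function(n) {
    out <- character()
    for (m in nodes) {
      preds <- edges$from[edges$to == m]
      dominates_pred <- any(vapply(preds, function(q)
        q %in% nodes && n %in% doms[[q]], TRUE))
      strictly_dominates_m <- n %in% setdiff(doms[[m]], m)
      if (dominates_pred && !strictly_dominates_m) out <- c(out, m)
    }
    sort(out)
  }), nodes)
  df
}

# Betweenness centrality by explicit shortest-path enumeration.
brute_betweenness <- function(net) {
  edges <- network_edges(net)
  nodes <- igraph::V(net$graph)$name
  btw <- setNames(numeric(length(nodes)), nodes)
  for (s in nodes) for (t in nodes) {
    if (s == t) next
    paths <- enumerate_paths(edges, s, t)
    if (!length(paths)) next
    len <- vapply(paths, length, 1L)
    shortest <- paths[len == min(len)]
    for (p in shortest)
      for (v in setdiff(p, c(s, t)))
        btw[v] <- btw[v] + 1 / length(shortest)
  }
  btw
}

# Shared small fixtures -------------------------------------------------

diamond_net <- function() {
  tiny_net(edge_df(c("A", "A", "B", "C"), c("B", "C", "D", "D")),
           source = "A", sinks = "D")
}

chain_net <- function(k = 4) {
  ids <- LETTERS[seq_len(k)]
  tiny_net(edge_df(ids[-k], ids[-1]), source = ids[1], sinks = ids[k])
}

toy_model_single <- function() {
  net <- make_toy_grn()
  entities <- list(protein_entity("IgG", 150))
  params <- kinetic_parameters(entities = "IgG")
  list(net = net, entities = entities, params = params,
       model = assemble_golgi_model(net, entities, params = params))
}
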