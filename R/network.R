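# Glycosylation reaction networks: construction, validation and I/O.

#' Golgi-resident enzyme vocabulary
#'
#' The eleven N-glycan processing enzymes recognised on network edges:
#' the glycosidases ManI and ManII and the glycosyltransferases GnTI,
#' GnTII, GnTIV, GnTV, b4GalT, a3SiaT, a6FucT, a3FucT and iGnT.
#'
#' @export
GLYCO_ENZYMES <- c("ManI", "ManII", "GnTI", "GnTII", "GnTIV", "GnTV",
                   "b4GalT", "a3SiaT", "a6FucT", "a3FucT", "iGnT")

#' Construct a glycosylation reaction network
#'
#' A reaction network is a directed acyclic graph whose nodes are glycan
#' structures (identified by LinearCode) and whose edges are biosynthetic
#' reactions labelled with the catalysing enzyme.
#'
#' @param nodes Data frame with columns `id`, `linear_code` and optionally
#'   `tag` (derived from the LinearCode when absent), `observed` (logical)
#'   and `observed_abundance` (percent).
#' @param edges Data frame with columns `from`, `to`, `enzyme`.
#' @param source Node id of the biosynthetic source (typically the M9
#'   high-mannose precursor).
#' @param sinks Character vector of sink node ids (typically the
#'   experimentally observed structures).
#' @param validate Check DAG structure, enzyme vocabulary and sink
#'   reachability (default `TRUE`).
#' @return An object of class `glyco_grn` wrapping an igraph graph with
#'   vertex attributes `linear_code`, `tag`, `observed`,
#'   `observed_abundance` and edge attribute `enzyme`.
#' @export
reaction_network <- function(nodes, edges, source = NULL, sinks = character(),
                             validate = TRUE) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("id", "linear_code") %in% names(nodes)))
    stop("schema error: nodes need columns 'id' and 'linear_code'")
  if (nrow(edges) && !all(c("from", "to", "enzyme") %in% names(edges)))
    stop("schema error: edges need columns 'from', 'to', 'enzyme'")
  if (anyNA(nodes$linear_code) || any(!nzchar(nodes$linear_code)))
    stop("schema error: every node needs a LinearCode string")
  if (anyDuplicated(nodes$id))
    stop("schema error: duplicated node ids")
  if (is.null(nodes$tag) || anyNA(nodes$tag)) {
    tags <- vapply(nodes$linear_code, function(lc) parse_linear_code(lc)$tag, "")
    if (is.null(nodes$tag)) nodes$tag <- tags
    else nodes$tag[is.na(nodes$tag)] <- tags[is.na(nodes$tag)]
  }
  if (is.null(nodes$observed)) nodes$observed <- FALSE
  if (is.null(nodes$observed_abundance)) nodes$observed_abundance <- NA_real_

  g <- igraph::graph_from_data_frame(
    if (nrow(edges)) edges[, c("from", "to", "enzyme")] else
      data.frame(from = character(), to = character(), enzyme = character()),
    directed = TRUE,
    vertices = nodes[, c("id", "linear_code", "tag", "observed",
                         "observed_abundance")])
  net <- structure(list(graph = g,
                        source = source,
                        sinks = as.character(sinks)),
                   class = "glyco_grn")
  if (validate) validate_network(net)
  net
}

#' Validate structural invariants of a reaction network
#'
#' Checks that the graph is a DAG, that every edge enzyme belongs to
#' [GLYCO_ENZYMES], and that every declared sink is reachable from the
#' source.
#'
#' @param net A `glyco_grn`.
#' @return `net`, invisibly; stops on violation.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "glyco_grn"))
  g <- net$graph
  if (!igraph::is_dag(g))
    stop("structural error: reaction network contains a directed cycle")
  enz <- igraph::E(g)$enzyme
  if (length(enz) && (anyNA(enz) || !all(enz %in% GLYCO_ENZYMES)))
    stop("schema error: edge enzyme(s) outside the enzyme vocabulary: ",
         paste(unique(enz[!enz %in% GLYCO_ENZYMES]), collapse = ", "))
  if (!is.null(net$source)) {
    if (!net$source %in% igraph::V(g)$name)
      stop("structural error: source node '", net$source, "' absent")
    if (length(net$sinks)) {
      missing <- setdiff(net$sinks, igraph::V(g)$name)
      if (length(missing))
        stop("structural error: sink node(s) absent: ",
             paste(missing, collapse = ", "))
      reach <- .reachable_from(g, net$source)
      bad <- setdiff(net$sinks, reach)
      if (length(bad))
        stop("structural error: sink(s) unreachable from source: ",
             paste(bad, collapse = ", "))
    }
  }
  invisible(net)
}

.reachable_from <- function(g, source) {
  names(igraph::subcomponent(g, source, mode = "out"))
}

#' @export
print.glyco_grn <- function(x, ...) {
  cat("<glyco_grn> ", igraph::vcount(x$graph), " nodes, ",
      igraph::ecount(x$graph), " edges\n", sep = "")
  if (!is.null(x$source)) cat("  source:", x$source, "\n")
  if (length(x$sinks)) cat("  sinks:", paste(x$sinks, collapse = ", "), "\n")
  invisible(x)
}

#' Node and edge tables of a reaction network
#'
#' @param net A `glyco_grn`.
#' @return `network_nodes`: data frame of node attributes;
#'   `network_edges`: data frame `from`, `to`, `enzyme`.
#' @export
network_nodes <- function(net) {
  v <- igraph::V(net$graph)
  data.frame(id = v$name, linear_code = v$linear_code, tag = v$tag,
             observed = v$observed, observed_abundance = v$observed_abundance,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname network_nodes
#' @export
network_edges <- function(net) {
  e <- igraph::as_data_frame(net$graph, what = "edges")
  names(e)[1:2] <- c("from", "to")
  e[, c("from", "to", "enzyme")]
}

#' Read or write a reaction network
#'
#' Supported formats: GraphML (node attributes `linear_code`, `tag`; edge
#' attribute `enzyme`; source and sinks stored as graph attributes), a
#' JSON dialect (`{"nodes": [...], "edges": [...], "source": id,
#' "sinks": [...]}`), and a plain edge-list CSV (`from,to,enzyme`, node
#' ids doubling as LinearCode strings).
#'
#' @param path File path.
#' @param format One of `"graphml"`, `"json"`, `"edge-csv"`; guessed from
#'   the file extension when omitted.
#' @param net A `glyco_grn` (for `save_network`).
#' @return `load_network` returns a validated `glyco_grn`; `save_network`
#'   returns `path` invisibly.
#' @export
load_network <- function(path, format = NULL) {
  format <- format %||% .guess_format(path)
  if (!file.exists(path)) stop("file not found: ", path)
  net <- switch(
    format,
    graphml = {
      g <- igraph::read_graph(path, format = "graphml")
      nodes <- data.frame(id = igraph::V(g)$name,
                          linear_code = igraph::vertex_attr(g, "linear_code"),
                          stringsAsFactors = FALSE)
      if (is.null(nodes$linear_code) || anyNA(nodes$linear_code))
        stop("schema error: GraphML node lacking 'linear_code'")
      tg <- igraph::vertex_attr(g, "tag")
      if (!is.null(tg)) nodes$tag <- tg
      ob <- igraph::vertex_attr(g, "observed")
      if (!is.null(ob)) nodes$observed <- as.logical(ob)
      oa <- igraph::vertex_attr(g, "observed_abundance")
      if (!is.null(oa)) nodes$observed_abundance <- as.numeric(oa)
      edges <- igraph::as_data_frame(g, what = "edges")
      if (nrow(edges) && is.null(edges$enzyme))
        stop("schema error: GraphML edge lacking 'enzyme'")
      src <- igraph::graph_attr(g, "source")
      snk <- igraph::graph_attr(g, "sinks")
      reaction_network(nodes, edges, source = src,
                       sinks = if (is.null(snk) || !nzchar(snk)) character()
                               else strsplit(snk, "\\|")[[1]])
    },
    json = {
      obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
      if (is.null(obj$nodes) || is.null(obj$nodes$linear_code) ||
          anyNA(obj$nodes$linear_code))
        stop("schema error: JSON node lacking 'linear_code'")
      edges <- obj$edges
      if (is.null(edges) || !nrow(as.data.frame(edges)))
        edges <- data.frame(from = character(), to = character(),
                            enzyme = character())
      reaction_network(obj$nodes, edges, source = obj$source,
                       sinks = obj$sinks %||% character())
    },
    `edge-csv` = {
      e <- utils::read.csv(path, stringsAsFactors = FALSE)
      if (!all(c("from", "to", "enzyme") %in% names(e)))
        stop("schema error: edge CSV needs columns from,to,enzyme")
      ids <- unique(c(e$from, e$to))
      reaction_network(data.frame(id = ids, linear_code = ids,
                                  stringsAsFactors = FALSE), e)
    },
    stop("unknown format: ", format))
  validate_network(net)
}

#' @rdname load_network
#' @export
save_network <- function(net, path, format = NULL) {
  stopifnot(inherits(net, "glyco_grn"))
  format <- format %||% .guess_format(path)
  switch(
    format,
    graphml = {
      g <- net$graph
      g <- igraph::set_graph_attr(g, "source", net$source %||% "")
      g <- igraph::set_graph_attr(g, "sinks", paste(net$sinks, collapse = "|"))
      igraph::write_graph(g, path, format = "graphml")
    },
    json = {
      obj <- list(nodes = network_nodes(net), edges = network_edges(net),
                  source = net$source, sinks = net$sinks)
      jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                           na = "null", digits = NA)
    },
    `edge-csv` = utils::write.csv(network_edges(net), path, row.names = FALSE),
    stop("unknown format: ", format))
  invisible(path)
}

.guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, graphml = "graphml", xml = "graphml", json = "json",
         csv = "edge-csv",
         stop("cannot guess network format from extension '", ext, "'"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select observed sink tags above an abundance threshold
#'
#' Returns the tags whose relative abundance strictly exceeds the
#' threshold in at least one protein entity, mirroring the rule of
#' retaining every structure found at over a given percent abundance
#' across all protein entities.
#'
#' @param profiles Data frame with columns `entity`, `tag`, `percent`.
#' @param threshold_percent Abundance cutoff in percent (default 1).
#' @return Character vector of retained tags (in order of first
#'   appearance); warns when empty.
#' @export
filter_observed_sinks <- function(profiles, threshold_percent = 1) {
  profiles <- as.data.frame(profiles)
  stopifnot(all(c("entity", "tag", "percent") %in% names(profiles)))
  if (any(profiles$percent < 0)) stop("abundances must be non-negative")
  keep <- vapply(split(profiles$percent, profiles$tag),
                 function(p) any(p > threshold_percent), logical(1))
  tags <- unique(profiles$tag)
  out <- tags[tags %in% names(keep)[keep]]
  if (!length(out))
    warning("no tag exceeds ", threshold_percent, "% in any entity")
  out
}

#' Prune a template network to the union of all shortest paths
#'
#' Shortest-path-finding (SPF) pruning: for each sink, every shortest
#' directed path (unit edge weights) from the source is enumerated and
#' their union taken as the pruned subgraph. The result is unique, so no
#' tie-breaking is required.
#'
#' @param template A `glyco_grn` template network.
#' @param source Source node id; defaults to `template$source`.
#' @param sinks Sink node ids; default `template$sinks`.
#' @return A pruned, validated `glyco_grn` with inherited attributes.
#' @export
prune_spf <- function(template, source = template$source,
                      sinks = template$sinks) {
  stopifnot(inherits(template, "glyco_grn"), !is.null(source), length(sinks) > 0)
  g <- template$graph
  keep_v <- character()
  keep_e <- integer()
  for (s in sinks) {
    ap <- tryCatch(
      igraph::all_shortest_paths(g, from = source, to = s, mode = "out"),
      error = function(e) NULL)
    paths <- if (is.null(ap)) list() else ap$vpaths %||% ap$res
    if (!length(paths))
      stop("sink '", s, "' unreachable from source '", source, "'")
    for (p in paths) {
      vn <- names(p)
      keep_v <- c(keep_v, vn)
      if (length(vn) > 1) {
        eids <- igraph::get_edge_ids(g, rbind(vn[-length(vn)], vn[-1]))
        keep_e <- c(keep_e, eids)
      }
    }
  }
  .induce_subnetwork(template, unique(keep_v), unique(keep_e),
                     source = source, sinks = sinks)
}

.induce_subnetwork <- function(template, vids, eids, source, sinks) {
  g <- template$graph
  sub <- igraph::subgraph_from_edges(g, igraph::E(g)[eids],
                                     delete.vertices = FALSE)
  sub <- igraph::induced_subgraph(sub, vids)
  net <- structure(list(graph = sub, source = source,
                        sinks = as.character(sinks)),
                   class = "glyco_grn")
  validate_network(net)
}

#' Prune a template network by minimum-flow reachability
#'
#' Minimum-flow-reachability (MFR) pruning attaches an artificial
#' SuperSource upstream of the source and a SuperSink downstream of every
#' sink, requires one unit of flow to reach each sink, and keeps the
#' template edges that carry positive flow. In `"minflow"` mode (the
#' default) the total flow routed over template edges is minimised
#' (min-cost flow, unit cost per edge), yielding the most parsimonious
#' subgraph that still connects the source to every sink; `"maxflow"`
#' mode keeps the edges used by a maximum SuperSource-to-SuperSink flow.
#' Deterministic tie-breaking: sinks are processed in order of
#' breadth-first distance from the source (ties broken by LinearCode),
#' and minimum-cost augmenting paths prefer lexicographically smaller
#' node sequences.
#'
#' @inheritParams prune_spf
#' @param mode `"minflow"` (default) or `"maxflow"`.
#' @return A pruned, validated `glyco_grn`.
#' @export
prune_mfr <- function(template, source = template$source,
                      sinks = template$sinks, mode = c("minflow", "maxflow")) {
  mode <- match.arg(mode)
  stopifnot(inherits(template, "glyco_grn"), !is.null(source), length(sinks) > 0)
  g <- template$graph
  reach <- .reachable_from(g, source)
  bad <- setdiff(sinks, reach)
  if (length(bad))
    stop("infeasible lower bounds: sink(s) unreachable from source: ",
         paste(bad, collapse = ", "))

  if (mode == "maxflow") {
    gg <- igraph::add_vertices(g, 2, name = c(".SuperSource", ".SuperSink"))
    cap <- rep(length(sinks), igraph::ecount(gg))
    add <- c(rbind(".SuperSource", source))
    for (s in sinks) add <- c(add, s, ".SuperSink")
    gg <- igraph::add_edges(gg, add)
    cap <- c(cap, length(sinks), rep(1, length(sinks)))
    mf <- igraph::max_flow(gg, ".SuperSource", ".SuperSink", capacity = cap)
    flow <- mf$flow[seq_len(igraph::ecount(g))]
    used <- which(flow > 1e-9)
  } else {
    used <- .min_cost_sink_flows(g, source, sinks)
  }
  ends <- igraph::ends(g, igraph::E(g)[used], names = TRUE)
  vids <- unique(c(source, sinks, as.vector(t(ends))))
  .induce_subnetwork(template, vids, used, source = source, sinks = sinks)
}

# Min-cost routing of one flow unit per sink (cost 1 per unit per template
# arc, arcs effectively uncapacitated by the SuperSource construction).
# With uniform arc costs the optimum decomposes: each unit independently
# follows a shortest source->sink path, so the minimum-total-flow subgraph
# is the union of one deterministically chosen shortest path per sink.
# Tie-break: walking back from the sink, prefer the lexicographically
# smallest predecessor on a shortest path. Returns template edge indices
# carrying positive flow.
.min_cost_sink_flows <- function(g, source, sinks) {
  dist <- igraph::distances(g, v = source, mode = "out")[1, ]
  # deterministic sink order: BFS distance from source, then lexicographic
  sinks <- sinks[order(dist[sinks], sinks)]
  used <- integer()
  for (s in sinks) {
    if (!is.finite(dist[s]))
      stop("infeasible lower bounds: sink '", s, "' unreachable")
    v <- s
    while (v != source) {
      preds <- names(igraph::neighbors(g, v, mode = "in"))
      preds <- preds[dist[preds] == dist[v] - 1]
      u <- sort(preds)[1]
      used <- c(used, igraph::get_edge_ids(g, c(u, v)))
      v <- u
    }
  }
  unique(used)
}
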