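test_that("networks round-trip through all three serialisation formats", {
  net <- make_toy_grn()
  # the edge-CSV dialect stores only (from, to, enzyme) with node ids
  # doubling as LinearCode strings, so it gets its own small fixture
  lc <- c("Ma3(Ma6)Mb4GNb4GN", "GNb2Ma3(Ma6)Mb4GNb4GN")
  csv_net <- reaction_network(
    data.frame(id = lc, linear_code = lc),
    data.frame(from = lc[1], to = lc[2], enzyme = "GnTI"))
  for (fmt in c("json", "graphml", "edge-csv")) {
    if (fmt == "edge-csv") net <- csv_net
    path <- tempfile(fileext = switch(fmt, json = ".json",
                                      graphml = ".graphml", `edge-csv` = ".csv"))
    save_network(net, path, fmt)
    back <- load_network(path, fmt)
    eo <- network_edges(net); eb <- network_edges(back)
    expect_setequal(paste(eo$from, eo$to, eo$enzyme),
                    paste(eb$from, eb$to, eb$enzyme))
    if (fmt != "edge-csv") {
      no <- network_nodes(net); nb <- network_nodes(back)
      expect_setequal(paste(no$id, no$linear_code, no$tag),
                      paste(nb$id, nb$linear_code, nb$tag))
      expect_identical(back$source, net$source)
      expect_setequal(back$sinks, net$sinks)
    }
    unlink(path)
  }
})

test_that("structural and schema violations are rejected on load", {
  # directed cycle
  expect_error(tiny_net(edge_df(c("A", "B"), c("B", "A"))), "cycle")
  # unknown enzyme
  expect_error(tiny_net(edge_df("A", "B", enzyme = "NotAnEnzyme")),
               "vocabulary")
  # node lacking a LinearCode in JSON
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(nodes = list(list(id = "A")),
                            edges = list()), path, auto_unbox = TRUE)
  expect_error(load_network(path, "json"), "linear_code")
  unlink(path)
  # declared sink unreachable from source
  expect_error(
    tiny_net(edge_df(c("A", "C"), c("B", "D")), source = "A", sinks = "D"),
    "unreachable")
})

test_that("observed sinks are selected by strict any-entity thresholding", {
  prof <- data.frame(entity = c("IgG", "IgG", "HCP", "HCP"),
                     tag = c("FA2", "M9", "M6", "M6"),
                     percent = c(52, 0.4, 0.5, 3))
  expect_identical(filter_observed_sinks(prof[1:2, ], 1), "FA2")
  # retained when any entity exceeds the threshold
  expect_true("M6" %in% filter_observed_sinks(prof, 1))
  # threshold 0 keeps every positive tag
  expect_setequal(filter_observed_sinks(prof, 0), c("FA2", "M9", "M6"))
  # exact threshold value is excluded (strict inequality)
  expect_identical(filter_observed_sinks(
    data.frame(entity = "x", tag = "t", percent = 1), 1), character(0)) |>
    suppressWarnings()
  expect_warning(filter_observed_sinks(
    data.frame(entity = "x", tag = "t", percent = 0.5), 1), "no tag")
})

test_that("SPF pruning keeps exactly the union of all shortest paths", {
  # diamond: both length-2 routes retained
  spf <- prune_spf(diamond_net())
  expect_equal(igraph::vcount(spf$graph), 4)
  expect_equal(igraph::ecount(spf$graph), 4)

  # chain: the chain itself
  spf2 <- prune_spf(chain_net(3))
  expect_equal(igraph::ecount(spf2$graph), 2)

  # a 3-edge detour next to a 2-edge path is excluded
  det <- tiny_net(edge_df(c("A", "B", "A", "X", "Y"),
                          c("B", "D", "X", "Y", "D")),
                  source = "A", sinks = "D")
  spf3 <- prune_spf(det)
  expect_setequal(igraph::V(spf3$graph)$name, c("A", "B", "D"))

  # oracle: SPF node set equals the union of explicit shortest paths
  net <- random_dag(10, seed = 7)
  sinks <- setdiff(igraph::V(net$graph)$name[igraph::degree(
    net$graph, mode = "out") == 0], "n01")
  spf4 <- prune_spf(net, "n01", sinks)
  expected <- character()
  for (s in sinks) {
    paths <- enumerate_paths(network_edges(net), "n01", s)
    len <- vapply(paths, length, 1L)
    expected <- union(expected, unlist(paths[len == min(len)]))
  }
  expect_setequal(igraph::V(spf4$graph)$name, expected)
  expect_error(prune_spf(diamond_net(), sinks = "Z"), "unreachable|absent")
})

test_that("MFR pruning routes one unit per sink with minimal total flow", {
  # diamond: exactly one branch survives
  mfr <- prune_mfr(diamond_net())
  expect_equal(igraph::vcount(mfr$graph), 3)
  expect_equal(igraph::ecount(mfr$graph), 2)

  # chain: unchanged
  expect_equal(igraph::ecount(prune_mfr(chain_net(4))$graph), 3)

  # two sinks on disjoint branches: both branches forced
  two <- tiny_net(edge_df(c("A", "A", "B", "C"), c("B", "C", "D", "E")),
                  source = "A", sinks = c("D", "E"))
  mfr2 <- prune_mfr(two)
  expect_setequal(igraph::V(mfr2$graph)$name, c("A", "B", "C", "D", "E"))

  expect_error(prune_mfr(tiny_net(edge_df("A", "B"), source = "A"),
                         sinks = "C"), "unreachable|absent")

  # maxflow mode also connects every sink
  mf <- prune_mfr(two, mode = "maxflow")
  expect_true(all(c("D", "E") %in% igraph::V(mf$graph)$name))
  validate_network(mf)
})

test_that("pruned networks satisfy the structural invariants and MFR <= SPF", {
  for (seed in c(3, 11, 42)) {
    net <- random_dag(11, seed = seed)
    sinks <- setdiff(igraph::V(net$graph)$name[igraph::degree(
      net$graph, mode = "out") == 0], "n01")
    spf <- prune_spf(net, "n01", sinks)
    mfr <- prune_mfr(net, "n01", sinks)
    for (pruned in list(spf, mfr)) {
      expect_true(igraph::is_dag(pruned$graph))
      expect_true(all(sinks %in% igraph::V(pruned$graph)$name))
      validate_network(pruned)
    }
    expect_lte(igraph::ecount(mfr$graph), igraph::ecount(spf$graph))
    cmp <- compare_graphs(mfr, spf)
    expect_true(cmp$subgraph_1_of_2)
  }
})

test_that("pruning output is independent of node declaration order", {
  nodes <- network_nodes(make_toy_grn())
  edges <- network_edges(make_toy_grn())
  net1 <- reaction_network(nodes, edges, source = "M9",
                           sinks = c("FA2G2S2", "FA4"))
  perm <- sample(nrow(nodes))
  net2 <- reaction_network(nodes[perm, ], edges[sample(nrow(edges)), ],
                           source = "M9", sinks = c("FA2G2S2", "FA4"))
  for (prune in list(prune_spf, prune_mfr)) {
    e1 <- network_edges(prune(net1))
    e2 <- network_edges(prune(net2))
    expect_setequal(paste(e1$from, e1$to), paste(e2$from, e2$to))
  }
})
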