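# PPI graph construction, topology metrics, modularity, communities

test_that("graph building thresholds, dedupes and restricts edges", {
  sp <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("protein1 protein2 combined_score",
               "A B 650", "A C 750", "B C 900", "A Z 999"), sp)
  bp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SymbolA\tSymbolB", "A\tC", "C\tD"), bp)
  nodes <- data.frame(id = c("A", "B", "C", "D"),
                      group = c("early", "early", "late", "late"),
                      stringsAsFactors = FALSE)
  g <- build_graph(nodes, string_links = sp, bioplex = bp)
  ed <- igraph::as_data_frame(g)
  key <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
  expect_setequal(key, c("A C", "B C", "C D"))
  # 650 edge dropped (strict > 700); Z outside node set skipped
  expect_equal(attr(g, "n_skipped_edges"), 1L)
  # A-C present in both sources: single edge, dual provenance
  expect_equal(ed$provenance[key == "A C"], "bioplex+string")
  expect_equal(attr(g, "summary")$n_edges, 3)
})

test_that("topology metrics match hand enumeration", {
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  expect_equal(network_metrics(k4)$density, 1.0)

  path3 <- igraph::make_graph(~ a - b, b - c)
  mp <- network_metrics(path3)
  expect_equal(mp$avg_shortest_path, (1 + 1 + 2) / 3)

  star <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:5))
  ms <- network_metrics(star)
  expect_equal(unname(ms$degree["hub"]), 5)
  expect_true(all(ms$degree[paste0("leaf", 1:5)] == 1))

  expect_error(network_metrics(igraph::make_empty_graph(1,
                                                        directed = FALSE)),
               ">= 2 nodes")
})

test_that("modularity matches its defining formula and brute force", {
  tri2 <- igraph::make_graph(c(1, 2, 2, 3, 3, 1, 4, 5, 5, 6, 6, 4),
                             directed = FALSE)
  igraph::V(tri2)$name <- letters[1:6]
  expect_equal(modularity_q(tri2, c(1, 1, 1, 2, 2, 2)), 0.5)
  # all nodes in one community: Q = 0
  expect_equal(modularity_q(tri2, rep(1, 6)), 0)

  # brute-force oracle on random 20-node graphs
  set.seed(3)
  for (i in 1:50) {
    g <- igraph::sample_gnp(20, 0.25)
    if (igraph::ecount(g) == 0) next
    igraph::V(g)$name <- sprintf("n%02d", 1:20)
    memb <- sample(1:4, 20, replace = TRUE)
    expect_equal(modularity_q(g, memb),
                 brute_force_modularity(g, memb), tolerance = 1e-12)
  }

  # invariance to node relabelling
  g <- igraph::sample_gnp(15, 0.3)
  igraph::V(g)$name <- sprintf("n%02d", 1:15)
  memb <- setNames(sample(1:3, 15, replace = TRUE),
                   igraph::V(g)$name)
  perm <- sample(15)
  g2 <- igraph::permute(g, perm)
  expect_equal(modularity_q(g2, memb), modularity_q(g, memb))

  expect_error(modularity_q(igraph::make_empty_graph(0), integer(0)),
               "empty")
})

test_that("greedy detection recovers planted communities", {
  # two 5-cliques joined by a bridge; exhaustive scan of all
  # 2-partitions confirms the cliques are the max-Q split
  g <- igraph::disjoint_union(igraph::make_full_graph(5),
                              igraph::make_full_graph(5))
  g <- igraph::add_edges(g, c(1, 6))
  igraph::V(g)$name <- letters[1:10]
  best_q <- -Inf; best_split <- NULL
  for (code in 0:(2^9 - 1)) {
    memb <- c(1, as.integer(intToBits(code))[1:9] + 1)
    q <- modularity_q(g, memb)
    if (q > best_q) { best_q <- q; best_split <- memb }
  }
  expect_equal(best_split, rep(c(1, 2), each = 5))
  gc <- greedy_communities(g, seed = 1)
  expect_equal(unname(gc$membership[1:5]),
               rep(gc$membership[[1]], 5))
  expect_equal(unname(gc$membership[6:10]),
               rep(gc$membership[[6]], 5))
  expect_equal(gc$Q, best_q)

  # edgeless graph: singleton communities, Q = 0 by convention
  e0 <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(e0)$name <- letters[1:4]
  g0 <- greedy_communities(e0)
  expect_equal(unname(g0$membership), 1:4)
  expect_equal(g0$Q, 0)

  # planted partition, 4 blocks x 8 nodes
  set.seed(5)
  blocks <- rep(1:4, each = 8)
  pm <- matrix(0.02, 4, 4); diag(pm) <- 0.5
  gp <- igraph::sample_sbm(32, pref.matrix = pm,
                           block.sizes = rep(8, 4))
  igraph::V(gp)$name <- sprintf("v%02d", 1:32)
  det <- greedy_communities(gp, seed = 1)
  expect_gte(mclust::adjustedRandIndex(det$membership, blocks), 0.9)
})

test_that("simulated networks show the early-core / late-module contrast", {
  net <- simulate_network(seed = 2)
  early <- net$nodes$id[net$nodes$group == "early"]
  late <- net$nodes$id[net$nodes$group == "late"]
  me <- network_metrics(net$graph, early)
  ml <- network_metrics(net$graph, late)
  expect_gt(me$density, ml$density)
  qe <- greedy_communities(igraph::induced_subgraph(net$graph, early))$Q
  ql <- greedy_communities(igraph::induced_subgraph(net$graph, late))$Q
  expect_gt(ql, qe)

  # p_out = 0: late subnetwork is a disjoint union of modules with
  # high best-partition modularity
  net0 <- simulate_network(p_out = 0, invariable_edges = 0, seed = 3)
  gl <- igraph::induced_subgraph(net0$graph,
                                 net0$nodes$id[net0$nodes$group ==
                                                 "late"])
  memb <- net0$nodes$module[net0$nodes$group == "late"]
  names(memb) <- net0$nodes$id[net0$nodes$group == "late"]
  expect_equal(igraph::components(gl)$no, length(unique(memb)))
  expect_gt(modularity_q(gl, memb), 0.5)

  # determinism
  n1 <- simulate_network(seed = 9)
  n2 <- simulate_network(seed = 9)
  expect_identical(igraph::as_edgelist(n1$graph),
                   igraph::as_edgelist(n2$graph))
})
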