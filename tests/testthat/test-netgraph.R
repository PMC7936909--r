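test_that("target assembly keeps known targets plus the top-k predictions", {
  known <- data.frame(source = "c1", target = "A", stringsAsFactors = FALSE)
  predicted <- data.frame(source = rep("c1", 20),
                          target = paste0("P", sprintf("%02d", 1:20)),
                          weight = seq(1, 0.05, length.out = 20),
                          stringsAsFactors = FALSE)
  asm <- assemble_targets(known, predicted, k = 15)
  expect_length(setdiff(asm$merged$c1, "A"), 15)

  # union deduplicates a predicted target already known
  predicted2 <- data.frame(source = "c1", target = c("A", "B"),
                           weight = c(0.9, 0.8), stringsAsFactors = FALSE)
  asm2 <- assemble_targets(known, predicted2, k = 15)
  expect_setequal(asm2$merged$c1, c("A", "B"))

  # tie at rank k resolved toward the lexicographically smaller symbol
  predicted3 <- data.frame(source = "c1", target = c("ZZ", "AA", "MM"),
                           weight = c(0.9, 0.5, 0.5), stringsAsFactors = FALSE)
  asm3 <- assemble_targets(known[0, ], predicted3, k = 2)
  expect_setequal(asm3$merged$c1, c("ZZ", "AA"))

  expect_error(assemble_targets(known, predicted, k = -1))
})

test_that("set intersection reports exact Venn counts", {
  r <- intersect_sets(c("A", "B", "C"), c("B", "C", "D"))
  expect_equal(r$intersection, c("B", "C"))
  expect_equal(r$venn, c(a_only = 1, b_only = 1, both = 2))
  expect_length(intersect_sets(c("A"), c("B"))$intersection, 0)
  sub <- intersect_sets(c("A", "B"), c("A", "B", "C"))
  expect_equal(sub$intersection, c("A", "B"))
})

test_that("component-target network keeps only putative edges and reports dropped compounds", {
  merged <- list(c1 = c("A", "B"), c2 = "B", c3 = c("X", "Y"))
  net <- build_ct_network(merged, putative = c("A", "B"))
  expect_equal(igraph::vcount(net$graph), 4)
  expect_equal(igraph::ecount(net$graph), 3)
  expect_equal(net$excluded_compounds, "c3")
  expect_setequal(igraph::V(net$graph)$layer, c("component", "target"))

  # duplicate target listings collapse to a single edge
  net2 <- build_ct_network(list(c1 = c("A", "A")), "A")
  expect_equal(igraph::ecount(net2$graph), 1)
})

test_that("node metrics match hand-computable geodesic structure", {
  path3 <- graph_from_bits(3, 3)$graph  # edges v2-v1, v3-v1
  m <- node_metrics(path3)
  expect_equal(m$betweenness[m$node == "v1"], 1)
  expect_equal(m$betweenness[m$node == "v2"], 0)

  star <- layered_graph(
    data.frame(id = c("hub", paste0("l", 1:4)), layer = "target"),
    data.frame(from = "hub", to = paste0("l", 1:4), kind = "ppi")
  )
  ms <- node_metrics(star)
  expect_equal(ms$betweenness[ms$node == "hub"], 1)  # raw 6 x 2/12
  expect_equal(ms$degree[ms$node == "hub"], 4L)

  cyc <- layered_graph(
    data.frame(id = paste0("v", 1:4), layer = "target"),
    data.frame(from = paste0("v", 1:4), to = paste0("v", c(2, 3, 4, 1)),
               kind = "ppi")
  )
  expect_equal(node_metrics(cyc)$betweenness, rep(1 / 6, 4))

  # degenerate graphs: betweenness defined as 0
  expect_equal(node_metrics(graph_from_bits(2, 1)$graph)$betweenness, c(0, 0))
})

test_that("betweenness agrees with exhaustive geodesic enumeration on small graphs", {
  # every graph on 3 and 4 nodes
  for (n in 3:4) {
    for (code in 0:(2^(n * (n - 1) / 2) - 1)) {
      gb <- graph_from_bits(n, code)
      expect_equal(node_metrics(gb$graph)$betweenness, enum_betweenness(gb$adj),
                   tolerance = 1e-12)
    }
  }
  # seeded samples of 5- and 6-node graphs
  set.seed(11)
  for (n in 5:6) {
    m <- n * (n - 1) / 2
    for (code in sample(0:(2^m - 1), 120)) {
      gb <- graph_from_bits(n, code)
      expect_equal(node_metrics(gb$graph)$betweenness, enum_betweenness(gb$adj),
                   tolerance = 1e-12)
    }
  }
})

test_that("network summary formulas and reachability accounting hold", {
  k3 <- graph_from_bits(3, 7)$graph
  s <- network_summary(k3)
  expect_equal(s$density, 1)
  expect_equal(s$heterogeneity, 0)
  expect_equal(s$reachable_fraction, 1)

  two_edges <- layered_graph(
    data.frame(id = paste0("v", 1:4), layer = "target"),
    data.frame(from = c("v1", "v3"), to = c("v2", "v4"), kind = "ppi")
  )
  s2 <- network_summary(two_edges)
  expect_equal(s2$reachable_ordered_pairs, 4L)
  expect_equal(s2$reachable_fraction, 1 / 3)

  # identities on random graphs: handshake and density = mean_degree/(N-1)
  set.seed(5)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    code <- floor(runif(1, 0, 2^min(n * (n - 1) / 2, 28)))
    gb <- graph_from_bits(n, code)
    s3 <- network_summary(gb$graph)
    expect_equal(sum(igraph::degree(gb$graph)), 2 * s3$n_edges)
    expect_equal(s3$density, s3$mean_degree / (s3$n_nodes - 1), tolerance = 1e-12)
  }
})

test_that("key-node screen uses strict dual thresholds", {
  m <- data.frame(node = c("a", "b", "c"), layer = "target",
                  degree = c(4L, 2L, 3L), betweenness = c(0.5, 0.1, 0.3))
  r <- screen_key_nodes(m)
  # means are (3, 0.3): only 'a' strictly exceeds both
  expect_equal(r$key_nodes$node, "a")
  expect_equal(r$n_above_degree, 1)
  # node at exactly the mean is excluded, so a regular graph yields none
  reg <- data.frame(node = c("x", "y"), layer = "target",
                    degree = c(3L, 3L), betweenness = c(0.2, 0.2))
  expect_equal(nrow(screen_key_nodes(reg)$key_nodes), 0)
  # |key| <= min of the single-threshold counts
  set.seed(9)
  for (i in 1:20) {
    mm <- data.frame(node = paste0("n", 1:30), layer = "target",
                     degree = rpois(30, 5), betweenness = runif(30))
    rr <- screen_key_nodes(mm)
    expect_lte(nrow(rr$key_nodes), min(rr$n_above_degree, rr$n_above_betweenness))
  }
})

test_that("PPI confidence filter is inclusive and drops isolated nodes", {
  ed <- data.frame(source = c("A", "B", "C", "D"),
                   target = c("B", "C", "D", "E"),
                   confidence = c(0.96, 0.95, 0.94, 0.50),
                   stringsAsFactors = FALSE)
  r <- filter_ppi(ed, cutoff = 0.95)
  expect_equal(r$n_edges, 2)
  expect_setequal(igraph::V(r$graph)$name, c("A", "B", "C"))
  expect_equal(r$avg_neighbors, 2 * 2 / 3)
  expect_equal(r$ranking$node[1], "B")

  empty <- filter_ppi(ed, cutoff = 0.99)
  expect_equal(empty$n_nodes, 0)
  expect_equal(nrow(empty$ranking), 0)
  expect_error(filter_ppi(ed, cutoff = 1.5))
})
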