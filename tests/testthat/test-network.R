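toy_edges <- function() {
  edge_table(c("A", "B", "C"), c("B", "C", "D"), c(0.9, 0.5, 0.95))
}

test_that("seed expansion keeps qualifying neighbors only", {
  net <- build_seed_network("A", toy_edges(), min_confidence = 0.7, hops = 1)
  nodes <- network_nodes(net)
  expect_setequal(nodes$node, c("A", "B"))
  ed <- network_edges(net)
  expect_equal(nrow(ed), 1L)
  expect_equal(ed$a, "A")
})

test_that("hops 0 keeps the seeds alone", {
  net <- build_seed_network("A", toy_edges(), min_confidence = 0.7, hops = 0)
  expect_equal(network_nodes(net)$node, "A")
  expect_equal(nrow(network_edges(net)), 0L)
})

test_that("two seeds at low cutoff pull in the full path", {
  net <- build_seed_network(c("A", "D"), toy_edges(),
                            min_confidence = 0.4, hops = 1)
  expect_setequal(network_nodes(net)$node, c("A", "B", "C", "D"))
  expect_equal(nrow(network_edges(net)), 3L)
})

test_that("seeds absent from the edge table stay as isolated flagged nodes", {
  net <- build_seed_network(c("A", "ZZ"), toy_edges(), 0.7, 1)
  nodes <- network_nodes(net)
  expect_true("ZZ" %in% nodes$node)
  expect_true(all(nodes$is_seed[nodes$node %in% c("A", "ZZ")]))
  expect_error(build_seed_network(character(), toy_edges()), "empty")
})

test_that("network construction is invariant to edge row order and
           monotone in the confidence cutoff", {
  set.seed(21)
  n <- 40
  a <- sprintf("N%02d", sample(n, 120, replace = TRUE))
  b <- sprintf("N%02d", sample(n, 120, replace = TRUE))
  keep <- a != b
  et <- edge_table(a[keep], b[keep], runif(sum(keep)))
  perm <- et[sample(nrow(et)), ]
  class(perm) <- class(et)
  n1 <- build_seed_network("N01", et, 0.3, 1)
  n2 <- build_seed_network("N01", perm, 0.3, 1)
  expect_equal(network_nodes(n1), network_nodes(n2))
  expect_equal(network_edges(n1), network_edges(n2))
  loose <- build_seed_network("N01", et, 0.1, 1)
  expect_true(all(network_nodes(n1)$node %in% network_nodes(loose)$node))
  expect_gte(nrow(network_edges(loose)), nrow(network_edges(n1)))
})

test_that("layer projection tags nodes and reports induced sizes", {
  net <- build_seed_network(c("A", "D"), toy_edges(), 0.4, 1)
  net <- project_layer(net, c("B", "C", "X"), "borrowed")
  nodes <- network_nodes(net)
  expect_setequal(nodes$node[nodes$layer == "borrowed"], c("B", "C"))
  expect_equal(net$layer_report$borrowed$n_nodes, 2L)
  net <- project_layer(net, c("C"), "intrinsic")
  nodes <- network_nodes(net)
  expect_equal(nodes$layer[nodes$node == "C"], "both")
  net0 <- project_layer(net, character(), "intrinsic")
  expect_equal(net0$layer_report$intrinsic$n_nodes, 0L)
  expect_error(project_layer(net, "A", "nonsense"), "layer_name")
})

test_that("hypergeometric upper tail matches exhaustive enumeration", {
  expect_equal(hypergeom_upper(5, 5, 5, 10), 1 / choose(10, 5),
               tolerance = 1e-12)
  expect_equal(hypergeom_upper(0, 5, 5, 10), 1)
  set.seed(33)
  for (i in 1:300) {
    N <- sample(2:60, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeom_upper(k, K, n, N), hyper_enum(k, K, n, N),
                 tolerance = 1e-12)
  }
  expect_error(hypergeom_upper(6, 5, 5, 10), "overlap")
})

test_that("connectivity test uses closed neighborhoods of both layers", {
  # path A-B, B-C, C-D plus isolated E: borrowed {A}, intrinsic {D}
  et <- edge_table(c("A", "B", "C", "E"), c("B", "C", "D", "F"),
                   rep(0.9, 4))
  net <- network_from_edges(et)
  net <- project_layer(net, "A", "borrowed")
  net <- project_layer(net, "D", "intrinsic")
  ct <- layer_connectivity_test(net)
  # neighborhoods {A,B} and {C,D} are disjoint: upper tail at 0 is 1
  expect_equal(ct$overlap_k, 0L)
  expect_equal(ct$p_value, 1)
  expect_equal(ct$universe_n, 6L)
  expect_equal(ct$layer1_k, 2L)
  net2 <- network_from_edges(et)
  net2 <- project_layer(net2, c("A", "C"), "borrowed")
  net2 <- project_layer(net2, "D", "intrinsic")
  ct2 <- layer_connectivity_test(net2)
  # borrowed nbhd {A,B,C,D}, intrinsic nbhd {C,D}: full overlap
  expect_equal(ct2$overlap_k, 2L)
  expect_equal(ct2$p_value, hyper_enum(2, 4, 2, 6), tolerance = 1e-12)
})

test_that("connectivity test requires both layers", {
  net <- network_from_edges(toy_edges())
  net <- project_layer(net, "A", "borrowed")
  expect_error(layer_connectivity_test(net), "both layers")
})

test_that("networks round-trip through export/import with summary counts", {
  net <- build_seed_network(c("A", "D"), toy_edges(), 0.4, 1)
  net <- project_layer(net, c("B"), "borrowed")
  net <- project_layer(net, c("C"), "intrinsic")
  d <- tempfile()
  export_network(net, d)
  back <- read_network(d)
  expect_equal(network_nodes(back), network_nodes(net))
  expect_equal(network_edges(back), network_edges(net))
  smry <- jsonlite::read_json(file.path(d, "summary.json"))
  expect_equal(smry$n_nodes, 4L)
  expect_equal(smry$layer_counts$borrowed, 1L)
  expect_equal(smry$layer_counts$both, 0L)
})

test_that("planted inter-layer wiring beats its degree-matched control", {
  truth <- simulation_truth()
  p_of <- function(truth, wiring) {
    et <- simulate_network(truth, wiring = wiring)
    net <- network_from_edges(et)
    net <- project_layer(net, truth$transfer_genes, "borrowed")
    net <- project_layer(net, truth$intrinsic_genes, "intrinsic")
    layer_connectivity_test(net)$p_value
  }
  wins <- 0L
  for (s in 1:20) {
    t2 <- truth
    t2$seed <- 1000L + s
    wins <- wins + (p_of(t2, "planted") < p_of(t2, "rewired_control"))
  }
  expect_gte(wins, 18L)
})
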