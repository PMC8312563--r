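test_that("closed-form values on canonical graphs are exact", {
  k4 <- complete_graph(4)
  expect_equal(clustering_coef(k4)$cp, 1)
  expect_equal(local_efficiency(k4)$loce, 1)
  expect_equal(global_efficiency(shortest_paths(complete_graph(7)))$ge, 1)

  p3 <- path_graph(3)
  expect_equal(characteristic_path_length(shortest_paths(p3))$lp, 4 / 3)
  expect_equal(global_efficiency(shortest_paths(p3))$ge, 5 / 6)

  # star: center carries all leaf pairs, no triangles anywhere
  st <- star_graph(5)
  expect_equal(clustering_coef(st)$cp, 0)
  expect_equal(local_efficiency(st)$loce, 0)
  expect_equal(betweenness_centrality(st)[1], choose(5, 2))
  expect_equal(degree_centrality(st), c(5L, rep(1L, 5)))

  # ring lattice k = 6: every node has clustering 3(k-2)/(4(k-1)) = 0.6
  lat <- generate_base_topology(90, 6, 0)
  expect_equal(clustering_coef(lat)$ci, rep(0.6, 90))
  expect_equal(degree_centrality(lat), rep(6L, 90))

  # 6-cycle: per-node distances 1,2,3,2,1 -> lp = 1.8
  expect_equal(characteristic_path_length(shortest_paths(cycle_graph(6)))$lp,
               1.8)
})

test_that("metrics match brute-force oracles on random small graphs", {
  set.seed(11)
  for (rep in 1:200) {
    n <- sample(4:8, 1)
    adj <- random_graph(n, runif(1, 0.2, 0.7))
    dm <- shortest_paths(adj)
    expect_equal(dm, oracle_distances(adj))
    expect_equal(clustering_coef(adj)$ci, oracle_clustering(adj))
    expect_equal(global_efficiency(dm)$ge, oracle_global_efficiency(adj))
    expect_equal(local_efficiency(adj)$loce, oracle_local_efficiency(adj)$global)
    expect_equal(betweenness_centrality(adj), oracle_betweenness(adj),
                 tolerance = 1e-12)
  }
})

test_that("metrics agree with igraph on larger random graphs", {
  skip_if_not_installed("igraph")
  set.seed(23)
  for (rep in 1:10) {
    adj <- random_graph(40, 0.1)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    dm <- shortest_paths(adj)
    expect_equal(dm, igraph::distances(g), ignore_attr = TRUE)
    expect_equal(betweenness_centrality(adj),
                 igraph::betweenness(g, directed = FALSE),
                 tolerance = 1e-10, ignore_attr = TRUE)
    ci <- igraph::transitivity(g, type = "local", isolates = "zero")
    # igraph returns NaN->0 for deg<2 under isolates="zero"
    expect_equal(clustering_coef(adj)$ci, ci, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("disconnected graphs use finite-only averaging and report the gap", {
  adj <- matrix(0L, 5, 5)
  adj[1, 2] <- adj[2, 1] <- 1L
  adj[3, 4] <- adj[4, 3] <- 1L   # node 5 isolated, two components
  dm <- shortest_paths(adj)
  pl <- characteristic_path_length(dm)
  expect_equal(pl$lp, 1)                      # only the two edges are finite
  expect_equal(pl$disconnected_pair_fraction, 16 / 20)
  expect_true(is.na(pl$li[5]))                # isolated node undefined
  ef <- global_efficiency(dm)
  expect_equal(ef$ei[5], 0)                   # isolated node zero efficiency
  expect_equal(ef$ge, 4 / 20)

  empty <- matrix(0L, 4, 4)
  pl0 <- characteristic_path_length(shortest_paths(empty))
  expect_true(is.na(pl0$lp))
  expect_equal(pl0$disconnected_pair_fraction, 1)
  expect_equal(global_efficiency(shortest_paths(empty))$ge, 0)
})

test_that("global and nodal metrics are invariant under node permutation", {
  set.seed(5)
  adj <- random_graph(30, 0.15)
  perm <- sample(30)
  padj <- adj[perm, perm]
  gm1 <- global_metrics(adj)
  gm2 <- global_metrics(padj)
  for (f in c("cp", "lp", "loce", "ge", "disconnected_pair_fraction")) {
    expect_equal(gm1[[f]], gm2[[f]], tolerance = 1e-12)
  }
  nm1 <- nodal_metrics(adj, node_labels = paste0("n", 1:30))
  nm2 <- nodal_metrics(padj, node_labels = paste0("n", 1:30))
  for (f in c("di", "ei", "bi", "ci", "li")) {
    expect_equal(nm2[[f]], nm1[[f]][perm], tolerance = 1e-12)
  }
})

test_that("edge addition shortens paths and raises efficiency; ge >= 1/lp", {
  set.seed(9)
  for (rep in 1:20) {
    adj <- random_graph(15, 0.25)
    dm <- shortest_paths(adj)
    if (any(!is.finite(dm))) next
    lp <- characteristic_path_length(dm)$lp
    ge <- global_efficiency(dm)$ge
    expect_gte(ge, 1 / lp - 1e-12)
    absent <- which(upper.tri(adj) & adj == 0)
    if (length(absent) == 0) next
    pick <- sample(absent, 1)
    adj2 <- adj
    adj2[pick] <- 1L
    adj2[lower.tri(adj2)] <- t(adj2)[lower.tri(adj2)]
    dm2 <- shortest_paths(adj2)
    expect_lte(characteristic_path_length(dm2)$lp, lp + 1e-12)
    expect_gte(global_efficiency(dm2)$ge, ge - 1e-12)
  }
})

test_that("handshake identity holds for degree centrality", {
  set.seed(3)
  for (rep in 1:10) {
    adj <- random_graph(25, 0.2)
    expect_equal(sum(degree_centrality(adj)), sum(adj))
  }
})
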