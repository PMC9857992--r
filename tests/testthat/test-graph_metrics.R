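complete_digraph <- function(n) {
  g <- igraph::make_full_graph(n, directed = TRUE)
  igraph::set_vertex_attr(g, "name", value = sprintf("n%d", seq_len(n)))
}

test_that("density and average degree follow their closed forms", {
  expect_equal(network_density(complete_digraph(3)), 1.0)
  ring10 <- make_toy_connectome("ring", 10)
  expect_equal(network_density(ring10), 10 / 90)
  expect_equal(average_degree(ring10), 1)
  edgeless <- igraph::make_empty_graph(4, directed = TRUE)
  expect_equal(average_degree(edgeless), 0)
  expect_error(network_density(igraph::make_empty_graph(1, directed = TRUE)),
               "2 nodes")
})

test_that("average path length handles rings, complete graphs and policies", {
  ring5 <- make_toy_connectome("ring", 5)
  expect_equal(average_path_length(ring5), 2.5)  # (1+2+3+4)/4
  expect_equal(average_path_length(complete_digraph(4)), 1.0)
  # strongly connected: both policies agree
  expect_equal(average_path_length(ring5, "require_connected"), 2.5)

  star <- make_toy_connectome("star_in", 5)
  expect_error(average_path_length(star, "require_connected"),
               "require_connected")
  # star_in: the only directed paths are the 4 leaf->hub edges
  expect_equal(average_path_length(star, "reachable_only"), 1.0)
  expect_equal(average_path_length(star, "all_pairs"), 4 / 20)
})

test_that("path lengths ignore synapse-count weights", {
  tab <- data.frame(pre = c("A", "B", "A"), post = c("B", "C", "C"),
                    count = c(10L, 10L, 1L))
  g <- collapse_to_simple(tab)
  d <- igraph::distances(g, v = "A", to = "C", mode = "out", weights = NA)
  expect_equal(average_path_length(g), mean(c(1, 1, 1)))  # A->B, B->C, A->C
  expect_equal(as.numeric(d), 1)
})

test_that("clustering matches the directed triangle-closure definition", {
  # directed 3-cycle: of the 4 admissible triangle configurations at each
  # node, 2 are realized
  tri <- collapse_to_simple(data.frame(pre = c("A", "B", "C"),
                                       post = c("B", "C", "A"), count = 1L))
  expect_equal(unname(clustering_coefficient(tri)), c(0.5, 0.5, 0.5))
  expect_equal(average_clustering(tri), 0.5)

  path <- collapse_to_simple(data.frame(pre = c("A", "B"),
                                        post = c("B", "C"), count = 1L))
  expect_equal(unname(clustering_coefficient(path, "B")), 0)

  # mixed reciprocal/one-way triangle; frozen from the reference directed
  # clustering of networkx on the same graph
  recip <- collapse_to_simple(data.frame(pre = c("A", "B", "B", "C", "A"),
                                         post = c("B", "A", "C", "B", "C"),
                                         count = 1L))
  expect_equal(unname(clustering_coefficient(recip)), c(1, 0.5, 1))

  # undirected projection mode: every triangle closes fully
  expect_equal(unname(clustering_coefficient(tri, mode = "undirected")),
               c(1, 1, 1))
  expect_equal(unname(clustering_coefficient(recip, mode = "undirected")),
               c(1, 1, 1))
})

test_that("degree distributions are normalized with a proper cdf", {
  star <- make_toy_connectome("star_in", 4)
  dd <- degree_distribution(star, "in")
  expect_equal(dd$support, c(0L, 3L))
  expect_equal(as.numeric(dd$pdf), c(3 / 4, 1 / 4))
  expect_equal(as.numeric(dd$cdf), c(1, 1 / 4))

  ring <- make_toy_connectome("ring", 5)
  for (dir in c("in", "out")) {
    dd <- degree_distribution(ring, dir)
    expect_equal(dd$support, 1L)
    expect_equal(as.numeric(dd$pdf), 1)
  }

  for (seed in 1:10) {
    g <- random_directed_graph(12, 0.2, seed)
    for (dir in c("in", "out")) {
      dd <- degree_distribution(g, dir)
      expect_equal(sum(dd$pdf), 1, tolerance = 1e-12)
      expect_true(all(diff(as.numeric(dd$cdf)) <= 1e-12))
      expect_equal(as.numeric(dd$cdf[1]), 1, tolerance = 1e-12)
      # zero-degree nodes are part of the support when present
      if (any(igraph::degree(g, mode = dir) == 0))
        expect_true(0L %in% dd$support)
    }
  }
})

test_that("asymmetry index behaves per definition and on the star fixture", {
  expect_equal(asymmetry_index(3, 1), 0.5)
  expect_equal(asymmetry_index(c(1, 4, 9), c(1, 4, 9)), c(0, 0, 0))
  expect_error(asymmetry_index(0, 0), "undefined")

  star <- make_toy_connectome("star_in", 4)
  # hub alpha = 1, each of 3 leaves alpha = -1: mean = (1 - 3)/4
  expect_equal(mean_asymmetry(star), -0.5)

  # isolated node policies
  g <- igraph::add_vertices(star, 1, name = "iso")
  expect_equal(mean_asymmetry(g, "skip"), -0.5)
  expect_equal(mean_asymmetry(g, "count_as_zero"), -2 / 5)
})

test_that("reversing every edge negates the mean asymmetry", {
  for (seed in 1:10) {
    g <- random_directed_graph(10, 0.25, seed + 50)
    if (igraph::ecount(g) == 0) next
    expect_equal(mean_asymmetry(igraph::reverse_edges(g)),
                 -mean_asymmetry(g), tolerance = 1e-12)
  }
})

test_that("small-worldness arithmetic and invariances hold", {
  # identical network and null: S = 1
  expect_equal(small_worldness_stats(0.2, 2.0, 0.2, 2.0), 1)
  # jointly rescaling the clustering pair leaves S unchanged
  expect_equal(small_worldness_stats(0.3, 2.5, 0.06, 3.1),
               small_worldness_stats(0.3 * 7, 2.5, 0.06 * 7, 3.1))
  expect_error(small_worldness_stats(0.2, 2, 0, 2.5), "C_rand")
  expect_error(small_worldness_stats(0.2, 0, 0.1, 2.5), "L")

  ring <- make_toy_connectome("ring", 6)
  ns <- structure(list(model = "ER", replicates = 1L, c_rand = 0.5,
                       l_rand = 3, c_rand_se = 0, l_rand_se = 0,
                       seed = 1L, pair_policy = "reachable_only"),
                  class = "null_ensemble_stats")
  expect_equal(small_worldness(ring, ns),
               (average_clustering(ring) / 0.5) /
                 (average_path_length(ring) / 3))
})

test_that("edge_set_diff counts added, pruned and common edges", {
  g1 <- collapse_to_simple(data.frame(pre = "A", post = "B", count = 1L))
  g2 <- collapse_to_simple(data.frame(pre = c("A", "B"), post = c("B", "C"),
                                      count = 1L))
  d <- edge_set_diff(g1, g2)
  expect_equal(d$common, 1L)
  expect_equal(d$added, 1L)
  expect_equal(d$pruned, 0L)

  same <- edge_set_diff(g2, g2)
  expect_equal(same$common, igraph::ecount(g2))
  expect_equal(same$added + same$pruned, 0L)

  # invariants on random snapshot pairs
  for (seed in 1:8) {
    ga <- random_directed_graph(9, 0.2, seed)
    gb <- random_directed_graph(9, 0.25, seed + 1000)
    d <- edge_set_diff(ga, gb)
    expect_equal(d$common + d$pruned, igraph::ecount(ga))
    expect_equal(d$common + d$added, igraph::ecount(gb))
  }
})

test_that("metrics_report aggregates all closed-form ring statistics", {
  rep5 <- metrics_report(make_toy_connectome("ring", 5))
  expect_equal(rep5$n, 5L)
  expect_equal(rep5$m, 5L)
  expect_equal(rep5$density, 0.25)
  expect_equal(rep5$mean_degree, 1)
  expect_equal(rep5$mean_clustering, 0)
  expect_equal(rep5$mean_path_length, 2.5)
  expect_equal(rep5$mean_asymmetry, 0)
  expect_true(all(is.na(c(rep5$s_er, rep5$s_dpr))))
})

test_that("metrics agree with brute-force oracles on random small graphs", {
  for (seed in 1:25) {
    n <- sample(3:8, 1)
    g <- random_directed_graph(n, stats::runif(1, 0.15, 0.6), seed + 200)
    adj <- adj_of(g)
    expect_equal(network_density(g), sum(adj) / (n * (n - 1)))
    expect_equal(unname(clustering_coefficient(g)), oracle_clustering(adj))
    if (any(adj)) {
      expect_equal(average_path_length(g), oracle_avg_path(adj))
      expect_equal(average_path_length(g, "all_pairs"),
                   oracle_avg_path(adj, all_pairs = TRUE))
      expect_equal(mean_asymmetry(g), oracle_mean_asymmetry(adj))
    }
    # handshake: in-stubs = out-stubs = M
    expect_equal(sum(igraph::degree(g, mode = "in")), igraph::ecount(g))
    expect_equal(sum(igraph::degree(g, mode = "out")), igraph::ecount(g))
  }
})

test_that("two_stage fixture metrics match the oracles", {
  g <- make_toy_connectome("two_stage", 9, seed = 1)
  adj <- adj_of(g)
  rep <- metrics_report(g)
  expect_equal(rep$mean_path_length, oracle_avg_path(adj))
  expect_equal(rep$mean_clustering, mean(oracle_clustering(adj)))
  expect_equal(rep$mean_asymmetry, oracle_mean_asymmetry(adj))
  expect_equal(rep$density, sum(adj) / (9 * 8))
})
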