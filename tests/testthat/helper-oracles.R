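# Brute-force oracles, independent of igraph: everything works on a plain
# logical adjacency matrix (adj[i, j] = TRUE iff edge i -> j).

adj_of <- function(g) {
  m <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  mode(m) <- "logical"
  m
}

# All-pairs shortest directed path lengths by Floyd-Warshall
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj] <- 1
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_avg_path <- function(adj, all_pairs = FALSE) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  diag(d) <- Inf
  fin <- is.finite(d)
  if (!any(fin)) return(NA_real_)
  if (all_pairs) sum(d[fin]) / (n * (n - 1)) else mean(d[fin])
}

# Directed (Fagiolo) local clustering by explicit triple loops: for each
# node count realized directed triangle configurations against the
# degree-determined maximum
oracle_clustering <- function(adj) {
  a <- adj * 1
  n <- nrow(a)
  vapply(seq_len(n), function(i) {
    tri <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      for (h in seq_len(n)) {
        if (h == i) next
        tri <- tri + (a[i, j] + a[j, i]) * (a[i, h] + a[h, i]) *
          (a[j, h] + a[h, j])
      }
    }
    d <- sum(a[i, ]) + sum(a[, i])
    dbi <- sum(a[i, ] * a[, i])
    denom <- 2 * (d * (d - 1) - 2 * dbi)
    if (denom <= 0) 0 else tri / denom
  }, numeric(1))
}

oracle_mean_asymmetry <- function(adj) {
  kin <- colSums(adj)
  kout <- rowSums(adj)
  tot <- kin + kout
  mean(((kin - kout) / tot)[tot > 0])
}

# Random simple directed graph as an igraph object, each ordered non-loop
# pair kept independently with probability p_edge
random_directed_graph <- function(n, p_edge, seed) {
  withr::with_seed(seed, {
    adj <- matrix(stats::runif(n * n) < p_edge, n, n)
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
    igraph::set_vertex_attr(g, "name", value = sprintf("n%d", seq_len(n)))
  })
}

# Random raw synapse table, possibly with self-loops, duplicates and
# zero-count rows
random_synapse_table <- function(n_rows, n_cells, seed) {
  withr::with_seed(seed, {
    cells <- sprintf("c%d", seq_len(n_cells))
    data.frame(pre = sample(cells, n_rows, replace = TRUE),
               post = sample(cells, n_rows, replace = TRUE),
               count = sample(0:4, n_rows, replace = TRUE),
               stringsAsFactors = FALSE)
  })
}

expect_simple_directed <- function(g) {
  expect_true(igraph::is_directed(g))
  expect_false(igraph::any_loop(g))
  expect_false(igraph::any_multiple(g))
}

edge_key_set <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  sort(paste(el[, 1], el[, 2]))
}
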