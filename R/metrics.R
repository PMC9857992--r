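#' Density of a directed network
#'
#' The density of a simple directed network is `rho = M / (N (N - 1))`: the
#' fraction of the `N (N - 1)` ordered non-loop node pairs that carry an
#' edge. Edge weights are ignored.
#'
#' @param g A directed igraph graph with at least 2 nodes.
#' @return The density, in `[0, 1]`.
#' @export
network_density <- function(g) {
  stopifnot(igraph::is_igraph(g), igraph::is_directed(g))
  n <- igraph::vcount(g)
  if (n < 2) stop("density is undefined for fewer than 2 nodes")
  igraph::ecount(g) / (n * (n - 1))
}

#' Average degree of a directed network
#'
#' For a directed network the mean in-degree and mean out-degree are equal:
#' every edge contributes one in-stub and one out-stub, so both averages are
#' `M / N`.
#'
#' @param g A directed igraph graph with at least 1 node.
#' @return Mean degree, edges per node.
#' @export
average_degree <- function(g) {
  stopifnot(igraph::is_igraph(g))
  n <- igraph::vcount(g)
  if (n < 1) stop("average degree is undefined for an empty node set")
  igraph::ecount(g) / n
}

#' Average shortest path length
#'
#' Directed shortest-path lengths in edges (weights ignored). The textbook
#' definition `L = sum(d_ij) / (N (N - 1))` assumes every ordered pair is
#' joined by a directed path, which fails for connectomes (sensory cells
#' have only out-edges). The `pair_policy` records how infinite distances
#' are handled:
#'
#' * `"reachable_only"` (default): average over ordered pairs joined by a
#'   directed path, dividing by the number of such pairs.
#' * `"all_pairs"`: sum finite distances but keep the strict `N (N - 1)`
#'   divisor.
#' * `"require_connected"`: error unless the graph is strongly connected.
#'
#' @param g A directed igraph graph with at least 2 nodes.
#' @param pair_policy How unreachable ordered pairs enter the average.
#' @return Mean shortest path length, in edges.
#' @export
average_path_length <- function(g,
                                pair_policy = c("reachable_only",
                                                "require_connected",
                                                "all_pairs")) {
  pair_policy <- match.arg(pair_policy)
  stopifnot(igraph::is_igraph(g), igraph::is_directed(g))
  n <- igraph::vcount(g)
  if (n < 2) stop("path length is undefined for fewer than 2 nodes")
  d <- igraph::distances(g, mode = "out", weights = NA)
  diag(d) <- Inf
  finite <- is.finite(d)
  n_pairs <- n * (n - 1)
  if (pair_policy == "require_connected" && sum(finite) < n_pairs)
    stop("graph is not strongly connected (pair_policy = 'require_connected')")
  if (!any(finite)) {
    warning("no ordered pair is joined by a directed path; returning NA")
    return(NA_real_)
  }
  if (pair_policy == "all_pairs") sum(d[finite]) / n_pairs else mean(d[finite])
}

# Undirected simple projection: reciprocal edge pairs collapse to one
# undirected edge, weights dropped.
undirected_projection <- function(g) {
  if ("weight" %in% igraph::edge_attr_names(g))
    g <- igraph::delete_edge_attr(g, "weight")
  igraph::as_undirected(g, mode = "collapse")
}

#' Local and average clustering coefficient
#'
#' The clustering coefficient of node `i` generalizes
#' `C_i = 2 E_i / (k_i (k_i - 1))` — the fraction of possible edges among
#' `i`'s `k_i` neighbours that actually exist — to directed graphs. The
#' default `mode = "directed"` is the directed coefficient of Fagiolo
#' (2007),
#' `C_i = (A + A^T)^3_ii / (2 (d_i (d_i - 1) - 2 d_i^bidir))`,
#' where `A` is the adjacency matrix, `d_i = k_in + k_out` the total
#' degree and `d_i^bidir` the number of reciprocal neighbours: the
#' fraction of all directed triangles through `i` that could exist, given
#' its degrees, that do. On a directed Erdős–Rényi graph its average
#' converges to the density `rho`, which is what makes the small-world
#' comparison against ER nulls meaningful. `mode = "undirected"` applies
#' the textbook formula to the undirected simple projection (reciprocal
#' pairs collapse to one edge). Under either mode nodes with fewer than
#' two neighbours contribute `C_i = 0`. The average `<C>` is the mean of
#' `C_i` over all `N` nodes.
#'
#' @param g A directed igraph graph.
#' @param v Optional vertex names or indices; default all nodes.
#' @param mode `"directed"` (Fagiolo) or `"undirected"` (projection).
#' @return `clustering_coefficient()`: a named numeric vector of `C_i`;
#'   `average_clustering()`: the scalar mean over all nodes.
#' @references Fagiolo, G. (2007). Clustering in complex directed
#'   networks. Physical Review E 76, 026107.
#' @export
clustering_coefficient <- function(g, v = NULL,
                                   mode = c("directed", "undirected")) {
  mode <- match.arg(mode)
  stopifnot(igraph::is_igraph(g), igraph::is_directed(g))
  if (mode == "undirected") {
    u <- undirected_projection(g)
    ci <- igraph::transitivity(u, type = "local", isolates = "zero")
  } else {
    a <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
    a[a > 1] <- 1
    u <- a + t(a)
    tri <- diag(u %*% u %*% u)
    d_tot <- rowSums(a) + colSums(a)
    d_bidir <- diag(a %*% a)
    denom <- 2 * (d_tot * (d_tot - 1) - 2 * d_bidir)
    ci <- ifelse(denom > 0, tri / denom, 0)
  }
  names(ci) <- igraph::V(g)$name
  if (is.null(v)) ci else ci[v]
}

#' @rdname clustering_coefficient
#' @export
average_clustering <- function(g, mode = c("directed", "undirected")) {
  if (igraph::vcount(g) < 1) stop("average clustering needs at least one node")
  mean(clustering_coefficient(g, mode = mode))
}

#' Empirical degree distribution of a directed network
#'
#' The probability density function `p(k) = N(k) / N`, where `N(k)` is the
#' number of nodes with in-degree (or out-degree) `k`, together with the
#' cumulative distribution `P(k) = P(x >= k) = sum_{x >= k} p(x)`. The
#' support is the set of observed degrees, including 0 when present
#' (connectomes contain cells with no out-edges).
#'
#' @param g A directed igraph graph with at least 1 node.
#' @param direction `"in"` or `"out"`.
#' @return An object of class `degree_distribution`: a list with elements
#'   `direction`, `support` (sorted observed degrees), `pdf` and `cdf`
#'   (named numeric vectors indexed by degree).
#' @export
degree_distribution <- function(g, direction = c("in", "out")) {
  direction <- match.arg(direction)
  stopifnot(igraph::is_igraph(g))
  n <- igraph::vcount(g)
  if (n < 1) stop("degree distribution needs at least one node")
  k <- igraph::degree(g, mode = direction, loops = FALSE)
  tab <- table(k)
  support <- as.integer(names(tab))
  pdf <- as.numeric(tab) / n
  cdf <- rev(cumsum(rev(pdf)))
  structure(list(direction = direction, support = support,
                 pdf = stats::setNames(pdf, support),
                 cdf = stats::setNames(cdf, support)),
            class = "degree_distribution")
}

#' @export
as.data.frame.degree_distribution <- function(x, ...) {
  data.frame(direction = x$direction, k = x$support,
             p_k = as.numeric(x$pdf), P_k = as.numeric(x$cdf))
}

#' @export
print.degree_distribution <- function(x, ...) {
  cat(sprintf("Empirical %s-degree distribution over %d observed degrees\n",
              x$direction, length(x$support)))
  print(utils::head(as.data.frame(x), 10L))
  if (length(x$support) > 10L) cat("...\n")
  invisible(x)
}

#' In/out-degree asymmetry index
#'
#' The per-node asymmetry index `alpha_i = (k_in - k_out) / (k_in + k_out)`
#' is positive when a node receives more edges than it sends. The network
#' average `<alpha>` is the mean of `alpha_i`; `alpha` is undefined for
#' isolated nodes (`k_in + k_out = 0`), which the mean handles according to
#' `zero_policy`: `"skip"` (default) excludes them and shrinks the divisor,
#' `"count_as_zero"` counts them as perfectly symmetric.
#'
#' @param k_in,k_out Nonnegative degree vectors of equal length with
#'   `k_in + k_out >= 1` elementwise.
#' @return `asymmetry_index()`: values in `[-1, 1]`; `mean_asymmetry()`:
#'   the network mean (NA if the graph has no non-isolated node under
#'   `"skip"`).
#' @examples
#' asymmetry_index(3, 1)  # 0.5: in-degree dominates
#' @export
asymmetry_index <- function(k_in, k_out) {
  stopifnot(length(k_in) == length(k_out), all(k_in >= 0), all(k_out >= 0))
  if (any(k_in + k_out == 0))
    stop("asymmetry index is undefined when k_in + k_out = 0")
  (k_in - k_out) / (k_in + k_out)
}

#' @rdname asymmetry_index
#' @param g A directed igraph graph.
#' @param zero_policy Treatment of isolated nodes, see Details.
#' @export
mean_asymmetry <- function(g, zero_policy = c("skip", "count_as_zero")) {
  zero_policy <- match.arg(zero_policy)
  stopifnot(igraph::is_igraph(g), igraph::is_directed(g))
  kin <- igraph::degree(g, mode = "in")
  kout <- igraph::degree(g, mode = "out")
  tot <- kin + kout
  if (zero_policy == "skip") {
    use <- tot > 0
    if (!any(use)) return(NA_real_)
    return(mean((kin[use] - kout[use]) / tot[use]))
  }
  a <- numeric(length(tot))
  nz <- tot > 0
  a[nz] <- (kin[nz] - kout[nz]) / tot[nz]
  mean(a)
}

#' Small-world coefficient
#'
#' `S = (<C> / C_rand) / (L / L_rand)`, where `C_rand` and `L_rand` are the
#' mean clustering and mean path length of a randomized null ensemble with
#' matching size. `S > 1` indicates clustering in excess of the null at
#' comparable path length. `small_worldness_stats()` applies the formula to
#' four scalar ingredients; `small_worldness()` measures `<C>` and `L` on a
#' graph and takes the null values from a [null_ensemble_stats()] object.
#'
#' @param c_mean,l_mean Mean clustering and mean path length of the network.
#' @param c_rand,l_rand The null-ensemble means; `c_rand` must be positive.
#' @return The dimensionless small-world coefficient.
#' @examples
#' small_worldness_stats(0.190, 2.058, 0.046, 2.588)  # about 5.19
#' @export
small_worldness_stats <- function(c_mean, l_mean, c_rand, l_rand) {
  if (any(c_rand <= 0)) stop("null clustering C_rand must be positive")
  if (any(l_mean <= 0)) stop("path length L must be positive")
  (c_mean / c_rand) / (l_mean / l_rand)
}

#' @rdname small_worldness_stats
#' @param g A directed igraph graph.
#' @param null_stats A [null_ensemble_stats()] object built on networks with
#'   the same N and M (ER) or the same degree sequence (DPR).
#' @param pair_policy Passed to [average_path_length()]; must match the
#'   policy used for the null ensemble.
#' @param clustering_mode Passed to [average_clustering()]; must match the
#'   mode used for the null ensemble.
#' @export
small_worldness <- function(g, null_stats, pair_policy = "reachable_only",
                            clustering_mode = "directed") {
  stopifnot(inherits(null_stats, "null_ensemble_stats"))
  small_worldness_stats(average_clustering(g, mode = clustering_mode),
                        average_path_length(g, pair_policy),
                        null_stats$c_rand, null_stats$l_rand)
}

#' Edges added, pruned and conserved between two networks
#'
#' Compares the ordered edge sets of two snapshots of a network (node sets
#' may differ). An edge is *added* when absent from the earlier graph and
#' present in the later one, *pruned* when present earlier and absent
#' later, and *common* when present in both.
#'
#' @param earlier,later Directed igraph graphs with named vertices.
#' @return An object of class `edge_set_diff`: a list with integer counts
#'   `common`, `added`, `pruned`. Invariants: `common + pruned` equals the
#'   earlier edge count and `common + added` the later one.
#' @export
edge_set_diff <- function(earlier, later) {
  key <- function(g) {
    el <- igraph::as_edgelist(g, names = TRUE)
    paste(el[, 1L], el[, 2L], sep = "\r")
  }
  e1 <- key(earlier)
  e2 <- key(later)
  structure(list(common = sum(e1 %in% e2),
                 added = sum(!(e2 %in% e1)),
                 pruned = sum(!(e1 %in% e2))),
            class = "edge_set_diff")
}

#' @export
print.edge_set_diff <- function(x, ...) {
  cat(sprintf("edge set diff: %d common, %d added, %d pruned\n",
              x$common, x$added, x$pruned))
  invisible(x)
}

#' Full structural-metrics report for one network
#'
#' One call computes every summary statistic used to characterize a
#' connectome: node and edge counts, density, mean degree, mean clustering,
#' mean path length, mean asymmetry index, and — when null ensembles are
#' supplied — the null means and small-world coefficients against the
#' Erdős–Rényi and degree-preserving ensembles.
#'
#' @param g A directed igraph graph.
#' @param null_er,null_dpr Optional [null_ensemble_stats()] objects for the
#'   ER and DPR ensembles.
#' @param pair_policy Passed to [average_path_length()].
#' @param zero_policy Passed to [mean_asymmetry()].
#' @param clustering_mode Passed to [average_clustering()]; use the same
#'   mode as the null ensembles.
#' @return A one-row data frame of class `metrics_report` with columns
#'   `n`, `m`, `density`, `mean_degree`, `mean_clustering`,
#'   `mean_path_length`, `mean_asymmetry`, `c_er`, `l_er`, `s_er`,
#'   `c_dpr`, `l_dpr`, `s_dpr` (null columns NA when no ensemble given).
#' @export
metrics_report <- function(g, null_er = NULL, null_dpr = NULL,
                           pair_policy = "reachable_only",
                           zero_policy = "skip",
                           clustering_mode = "directed") {
  stopifnot(igraph::is_igraph(g), igraph::is_directed(g))
  n <- igraph::vcount(g)
  out <- data.frame(
    n = n,
    m = igraph::ecount(g),
    density = if (n >= 2) network_density(g) else NA_real_,
    mean_degree = if (n >= 1) average_degree(g) else NA_real_,
    mean_clustering = if (n >= 1) average_clustering(g, mode = clustering_mode)
                      else NA_real_,
    mean_path_length = if (n >= 2) average_path_length(g, pair_policy)
                       else NA_real_,
    mean_asymmetry = if (n >= 1) mean_asymmetry(g, zero_policy) else NA_real_,
    c_er = NA_real_, l_er = NA_real_, s_er = NA_real_,
    c_dpr = NA_real_, l_dpr = NA_real_, s_dpr = NA_real_)
  if (!is.null(null_er)) {
    stopifnot(inherits(null_er, "null_ensemble_stats"))
    if (null_er$model != "ER") warning("null_er does not carry the ER tag")
    out$c_er <- null_er$c_rand
    out$l_er <- null_er$l_rand
    out$s_er <- small_worldness(g, null_er, pair_policy, clustering_mode)
  }
  if (!is.null(null_dpr)) {
    stopifnot(inherits(null_dpr, "null_ensemble_stats"))
    if (null_dpr$model != "DPR") warning("null_dpr does not carry the DPR tag")
    out$c_dpr <- null_dpr$c_rand
    out$l_dpr <- null_dpr$l_rand
    out$s_dpr <- small_worldness(g, null_dpr, pair_policy, clustering_mode)
  }
  class(out) <- c("metrics_report", "data.frame")
  out
}
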