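#' Erdős–Rényi random directed graph with a fixed edge count
#'
#' Samples `m` distinct ordered node pairs uniformly from the `n (n - 1)`
#' possible directed non-loop pairs, so the edge count is exactly `m` in
#' every draw. Isolated nodes are allowed.
#'
#' @param n Number of nodes.
#' @param m Number of edges, `0 <= m <= n (n - 1)`.
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @return A simple directed igraph graph with `n` named nodes and `m`
#'   edges.
#' @export
er_random <- function(n, m, seed = 1L) {
  stopifnot(is.numeric(n), n >= 1, is.numeric(m))
  if (m < 0 || m > n * (n - 1))
    stop("m must lie in [0, n(n-1)] for a simple directed graph")
  g <- withr::with_seed(as.integer(seed),
                        igraph::sample_gnm(n, m, directed = TRUE,
                                           loops = FALSE))
  igraph::set_vertex_attr(g, "name", value = sprintf("n%d", seq_len(n)))
}

#' Degree-preserving randomization by directed double-edge swaps
#'
#' Repeatedly picks two existing edges `(u1, v1)` and `(u2, v2)`, deletes
#' them and adds `(u1, v2)` and `(u2, v1)`. A candidate swap is rejected —
#' counted as an attempt, not a success — when it would create a self-loop
#' (`u1 = v2` or `u2 = v1`) or a duplicate of an existing edge. Every
#' node's in-degree and out-degree are conserved exactly. The run performs
#' `round(swap_factor * M)` successful swaps; on swap-rigid graphs (for
#' example a directed 3-cycle, where no legal swap exists) it gives up
#' after `100 x` that many attempts and returns the current state with a
#' warning.
#'
#' @param g A directed igraph graph with at least 2 edges.
#' @param swap_factor Successful swaps per edge; 10 is enough mixing for
#'   graphs of connectome size.
#' @param seed Integer seed.
#' @return A rewired simple directed igraph graph with the identical in-
#'   and out-degree sequences (edge weights are dropped: randomization is
#'   topological).
#' @export
dpr_randomize <- function(g, swap_factor = 10, seed = 1L) {
  stopifnot(igraph::is_igraph(g), igraph::is_directed(g), swap_factor > 0)
  m <- igraph::ecount(g)
  n <- igraph::vcount(g)
  if (m < 2) stop("degree-preserving rewiring needs at least 2 edges")
  el <- igraph::as_edgelist(g, names = FALSE)
  eu <- as.integer(el[, 1L])
  ev <- as.integer(el[, 2L])
  adj <- matrix(FALSE, n, n)
  adj[el] <- TRUE
  target <- max(1L, as.integer(round(swap_factor * m)))
  budget <- 100L * target
  done <- 0L
  att <- 0L
  withr::with_seed(as.integer(seed), {
    while (done < target && att < budget) {
      att <- att + 1L
      ij <- sample.int(m, 2L)
      u1 <- eu[ij[1L]]; v1 <- ev[ij[1L]]
      u2 <- eu[ij[2L]]; v2 <- ev[ij[2L]]
      if (u1 == v2 || u2 == v1) next
      if (adj[u1, v2] || adj[u2, v1]) next
      adj[u1, v1] <- FALSE; adj[u2, v2] <- FALSE
      adj[u1, v2] <- TRUE; adj[u2, v1] <- TRUE
      ev[ij[1L]] <- v2; ev[ij[2L]] <- v1
      done <- done + 1L
    }
  })
  if (done < target)
    warning("dpr_randomize: only ", done, " of ", target, " swaps succeeded ",
            "within the attempt budget; returning the current state")
  out <- igraph::make_empty_graph(n, directed = TRUE)
  out <- igraph::add_edges(out, as.vector(rbind(eu, ev)))
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- sprintf("n%d", seq_len(n))
  igraph::set_vertex_attr(out, "name", value = nm)
}

#' Null-ensemble clustering and path length
#'
#' Generates `replicates` randomized networks — Erdős–Rényi with the same
#' `N` and `M`, or degree-preserving rewirings of `g` — and averages their
#' mean clustering and mean path length into `C_rand` and `L_rand`, the
#' ingredients of the small-world coefficient. Per-replicate seeds are
#' derived deterministically from the master seed, so the same call is
#' bit-reproducible.
#'
#' @param g The reference directed igraph graph.
#' @param model `"er"` or `"dpr"` (case-insensitive).
#' @param replicates Number of randomized networks, at least 1.
#' @param seed Master integer seed.
#' @param pair_policy Passed to [average_path_length()] for every replicate;
#'   use the same policy as for the real network.
#' @param swap_factor Passed to [dpr_randomize()] when `model = "dpr"`.
#' @param clustering_mode Passed to [average_clustering()] for every
#'   replicate.
#' @return An object of class `null_ensemble_stats`: a list with `model`
#'   (`"ER"` or `"DPR"`), `replicates`, `c_rand`, `l_rand`, their standard
#'   errors `c_rand_se` and `l_rand_se`, `seed` and `pair_policy`.
#' @export
null_ensemble_stats <- function(g, model = c("er", "dpr"), replicates,
                                seed = 1L, pair_policy = "reachable_only",
                                swap_factor = 10,
                                clustering_mode = "directed") {
  model <- match.arg(tolower(model[1L]), c("er", "dpr"))
  stopifnot(is.numeric(replicates), replicates >= 1)
  replicates <- as.integer(replicates)
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  rep_seeds <- withr::with_seed(as.integer(seed),
                                sample.int(2147483646L, replicates))
  cs <- numeric(replicates)
  ls <- numeric(replicates)
  for (r in seq_len(replicates)) {
    gr <- if (model == "er") er_random(n, m, rep_seeds[r])
          else dpr_randomize(g, swap_factor, rep_seeds[r])
    cs[r] <- average_clustering(gr, mode = clustering_mode)
    ls[r] <- average_path_length(gr, pair_policy)
  }
  structure(list(model = toupper(model),
                 replicates = replicates,
                 c_rand = mean(cs),
                 l_rand = mean(ls),
                 c_rand_se = stats::sd(cs) / sqrt(replicates),
                 l_rand_se = stats::sd(ls) / sqrt(replicates),
                 seed = as.integer(seed),
                 pair_policy = pair_policy),
            class = "null_ensemble_stats")
}

#' @export
print.null_ensemble_stats <- function(x, ...) {
  cat(sprintf("%s null ensemble (%d replicates, seed %d)\n",
              x$model, x$replicates, x$seed))
  cat(sprintf("  C_rand = %.4f (se %.2g)\n  L_rand = %.4f (se %.2g)\n",
              x$c_rand, x$c_rand_se, x$l_rand, x$l_rand_se))
  invisible(x)
}
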