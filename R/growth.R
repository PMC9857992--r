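#' Parameter bundle for the network-evolution model
#'
#' The model grows a simple directed network over `n` fixed nodes until it
#' holds exactly `m` edges. At each time step an existing edge is removed
#' uniformly at random with probability `p` (`p < 0.5`, a no-op while the
#' network is empty); otherwise a new edge is added by preferential
#' attachment, with the source drawn proportionally to `k_out + b` and the
#' target proportionally to `k_in + a`. `a` and `b` are the initial
#' attractiveness of in-degrees and out-degrees: the additive constants
#' that give degree-zero nodes a nonzero chance of gaining edges, and whose
#' imbalance drives the in/out-degree asymmetry of the grown network.
#'
#' @param n Number of nodes (all present from t = 0).
#' @param m Target edge count, at most `n (n - 1)`.
#' @param a Initial attractiveness for in-degrees, positive real.
#' @param b Initial attractiveness for out-degrees, positive real.
#' @param p Edge-removal probability, in `[0, 0.5)`.
#' @param seed Integer seed; a fixed seed makes [simulate_growth()]
#'   bit-reproducible.
#' @return An object of class `model_params`.
#' @examples
#' model_params(n = 20, m = 40, a = 2, b = 3, p = 0.1, seed = 1)
#' @export
model_params <- function(n, m, a, b, p = 0.1, seed = 1L) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1,
            is.numeric(m), length(m) == 1L, m >= 0)
  if (m > n * (n - 1))
    stop("m exceeds the n(n-1) capacity of a simple directed graph")
  if (!is.numeric(a) || a <= 0 || !is.numeric(b) || b <= 0)
    stop("initial attractiveness a and b must be positive")
  if (!is.numeric(p) || p < 0 || p >= 0.5)
    stop("edge-removal probability p must satisfy 0 <= p < 0.5")
  structure(list(n = as.integer(n), m = as.integer(m), a = a, b = b, p = p,
                 seed = as.integer(seed)),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "network-evolution model: n = %d, m = %d, a = %g, b = %g, p = %g, seed = %d\n",
    x$n, x$m, x$a, x$b, x$p, x$seed))
  invisible(x)
}

#' Preferential-attachment endpoint probabilities
#'
#' For the current state of a network, the probability that node `i` is
#' chosen as the source of the next edge is `(k_i_out + b) / sum(k_out + b)`
#' and as the target `(k_i_in + a) / sum(k_in + a)`. On an all-isolated
#' network both distributions are uniform.
#'
#' @param g A directed igraph graph.
#' @param a,b Positive initial attractiveness for in- and out-degrees.
#' @return A list with components `source` and `target`, each a probability
#'   vector over the nodes (named when the graph is) summing to 1.
#' @export
attachment_probabilities <- function(g, a, b) {
  stopifnot(igraph::is_igraph(g), igraph::is_directed(g))
  if (!is.numeric(a) || a <= 0 || !is.numeric(b) || b <= 0)
    stop("initial attractiveness a and b must be positive")
  kout <- igraph::degree(g, mode = "out")
  kin <- igraph::degree(g, mode = "in")
  list(source = (kout + b) / sum(kout + b),
       target = (kin + a) / sum(kin + a))
}

#' Simulate the network-evolution model
#'
#' Runs the add/remove process of [model_params()] until the edge count
#' first reaches `m` (or `t_max` steps have elapsed). An addition draws the
#' source and target independently from the attachment probabilities; a
#' drawn pair that would form a self-loop or duplicate an existing edge is
#' rejected and the whole pair redrawn, up to 10^4 attempts before the run
#' aborts with a saturation error. A removal step drawn while the network
#' is empty is a no-op, but time still advances.
#'
#' @param params A [model_params()] object.
#' @param record_trajectory If `TRUE`, also return the per-step edge count
#'   `E(t)`.
#' @param t_max Optional step cap; by default the run ends only when the
#'   edge count reaches `m`.
#' @param checkpoints Optional increasing integer step indices at which to
#'   snapshot every node's in-degree (columns left `NA` if the run stops
#'   first).
#' @return With neither `record_trajectory` nor `checkpoints`: a simple
#'   directed igraph graph with exactly `n` nodes and (when `t_max` does
#'   not intervene) exactly `m` edges. Otherwise a list of class
#'   `growth_sim` with elements `graph`, `trajectory` (data frame `t`,
#'   `edges`, when recorded), `kin_checkpoints` (nodes x checkpoints
#'   matrix), `checkpoints`, `first_in_time` (step at which each node
#'   gained its first in-edge, `NA` if never) and `params`.
#' @examples
#' g <- simulate_growth(model_params(20, 40, a = 2, b = 3, p = 0.1, seed = 1))
#' igraph::ecount(g)  # exactly 40
#' @export
simulate_growth <- function(params, record_trajectory = FALSE, t_max = Inf,
                            checkpoints = NULL) {
  stopifnot(inherits(params, "model_params"))
  n <- params$n
  m_target <- params$m
  a <- params$a
  b <- params$b
  p <- params$p
  extras <- record_trajectory || !is.null(checkpoints)
  cps <- sort(unique(as.integer(checkpoints)))

  res <- withr::with_seed(params$seed, {
    kin <- numeric(n)
    kout <- numeric(n)
    adj <- matrix(FALSE, n, n)
    eu <- integer(max(m_target, 1L))
    ev <- integer(max(m_target, 1L))
    e_count <- 0L
    t <- 0L
    hist_cap <- as.integer(min(t_max, ceiling(m_target / max(1 - 2 * p, 1e-9)))
                           + 1000L)
    e_hist <- if (record_trajectory) integer(hist_cap) else NULL
    kin_cp <- if (length(cps)) matrix(NA_real_, n, length(cps)) else NULL
    cp_i <- 1L
    first_in <- rep(NA_integer_, n)

    while (e_count < m_target && t < t_max) {
      t <- t + 1L
      if (stats::runif(1L) < p) {
        if (e_count > 0L) {
          j <- sample.int(e_count, 1L)
          adj[eu[j], ev[j]] <- FALSE
          kout[eu[j]] <- kout[eu[j]] - 1
          kin[ev[j]] <- kin[ev[j]] - 1
          eu[j] <- eu[e_count]
          ev[j] <- ev[e_count]
          e_count <- e_count - 1L
        }
      } else {
        attempts <- 0L
        repeat {
          attempts <- attempts + 1L
          if (attempts > 10000L)
            stop("saturation: no admissible (source, target) pair found ",
                 "after 10000 draws; the graph cannot grow further")
          s <- sample.int(n, 1L, prob = kout + b)
          tg <- sample.int(n, 1L, prob = kin + a)
          if (s != tg && !adj[s, tg]) break
        }
        e_count <- e_count + 1L
        eu[e_count] <- s
        ev[e_count] <- tg
        adj[s, tg] <- TRUE
        kout[s] <- kout[s] + 1
        kin[tg] <- kin[tg] + 1
        if (is.na(first_in[tg])) first_in[tg] <- t
      }
      if (record_trajectory) {
        if (t > length(e_hist)) e_hist <- c(e_hist, integer(length(e_hist)))
        e_hist[t] <- e_count
      }
      if (!is.null(kin_cp) && cp_i <= length(cps) && t == cps[cp_i]) {
        kin_cp[, cp_i] <- kin
        cp_i <- cp_i + 1L
      }
    }
    list(eu = eu[seq_len(e_count)], ev = ev[seq_len(e_count)], t = t,
         e_hist = if (record_trajectory) e_hist[seq_len(t)] else NULL,
         kin_cp = kin_cp, first_in = first_in)
  })

  g <- igraph::make_empty_graph(n, directed = TRUE)
  if (length(res$eu))
    g <- igraph::add_edges(g, as.vector(rbind(res$eu, res$ev)))
  g <- igraph::set_vertex_attr(g, "name", value = sprintf("n%d", seq_len(n)))
  if (!extras) return(g)
  structure(list(
    graph = g,
    trajectory = if (record_trajectory)
      data.frame(t = seq_len(res$t), edges = res$e_hist) else NULL,
    kin_checkpoints = res$kin_cp,
    checkpoints = cps,
    first_in_time = res$first_in,
    params = params), class = "growth_sim")
}

#' Expected edge count of the evolution model
#'
#' In expectation the edge count grows as `E(t) = (1 - 2 p) t`: each step
#' adds an edge with probability `1 - p` and removes one with probability
#' `p`, for a net drift of `1 - 2 p` edges per step.
#'
#' @param t Step count(s).
#' @param p Edge-removal probability, in `[0, 0.5)`.
#' @return Expected edge count(s).
#' @export
expected_edges <- function(t, p) {
  if (any(p < 0 | p >= 0.5)) stop("p must satisfy 0 <= p < 0.5")
  (1 - 2 * p) * t
}

#' Closed-form expected in-degree in the small-p limit
#'
#' When removals are negligible (`p -> 0`), the continuum-theory rate
#' equation for a node that gained its first in-edge at time `t_i` (initial
#' condition `k(t_i) = 1`) integrates to
#' `k_in(t) = (1 + a) (N a + t) / (N a + t_i) - a` for `t >= t_i`, so each
#' node's expected in-degree eventually grows linearly in time. The
#' out-degree analogue substitutes the out-attractiveness `b` for `a`.
#' As `a` grows large, attachment becomes uniform and the curve approaches
#' `1 + (t - t_i) / N`.
#'
#' @param t Time(s), `t >= t_i`.
#' @param t_i Time the node acquired its first in-edge.
#' @param a Initial attractiveness for in-degrees, positive.
#' @param n Number of nodes.
#' @return Expected in-degree at each `t`.
#' @export
expected_indegree_smallp <- function(t, t_i, a, n) {
  if (!is.numeric(a) || a <= 0) stop("a must be positive")
  stopifnot(is.numeric(n), n >= 1)
  if (any(t < t_i)) stop("t must be >= t_i")
  (1 + a) * (n * a + t) / (n * a + t_i) - a
}

#' Numerically integrate the continuum-theory rate equation
#'
#' The expected in-degree of a node obeys
#' `dk/dt = (1 - p) (k + a) / ((1 - 2 p) t + N a) - p / ((1 - 2 p) t)`,
#' using the mean-field substitutions `sum(k_in) + a = (1 - 2 p) t + N a`
#' for the attachment denominator and `E(t) = (1 - 2 p) t` for the edge
#' count in the removal term, with initial condition `k(t_i) = 1`. This
#' ODE solution is the reference against which simulated degree
#' trajectories and the small-`p` closed form are checked; the general
#' closed form is not evaluated symbolically.
#'
#' @param a Initial attractiveness for in-degrees, positive (use `b` for
#'   the out-degree analogue).
#' @param p Edge-removal probability, in `[0, 0.5)`.
#' @param n Number of nodes.
#' @param t_i Start time, equal to the first grid point; must be positive
#'   when `p > 0` (the `1/E` removal term is singular at `t = 0`).
#' @param t_grid Strictly increasing times starting at `t_i`.
#' @return A data frame with columns `t` and `k_in`.
#' @export
integrate_rate_equation <- function(a, p, n, t_i, t_grid) {
  if (!is.numeric(a) || a <= 0) stop("a must be positive")
  if (!is.numeric(p) || p < 0 || p >= 0.5)
    stop("p must satisfy 0 <= p < 0.5")
  stopifnot(is.numeric(n), n >= 1, length(t_grid) >= 2,
            all(diff(t_grid) > 0))
  if (t_grid[1L] <= 0 && p > 0)
    stop("t_grid must start at t_i > 0 when p > 0 ",
         "(the 1/E removal term is singular at t = 0)")
  if (abs(t_grid[1L] - t_i) > 1e-9)
    stop("t_grid must start at t_i")
  rhs <- function(t, y, parms) {
    denom <- (1 - 2 * p) * t + n * a
    removal <- if (p > 0) p / ((1 - 2 * p) * t) else 0
    list((1 - p) * (y + a) / denom - removal)
  }
  sol <- deSolve::ode(y = c(k = 1), times = t_grid, func = rhs, parms = NULL,
                      rtol = 1e-9, atol = 1e-10)
  data.frame(t = as.numeric(sol[, "time"]), k_in = as.numeric(sol[, "k"]))
}
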