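---
title: "Growth of directed networks with unequal initial attractiveness: model, metrics, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth of directed networks with unequal initial attractiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormnet)
```

## The problem

Chemical synaptic networks are directed: signal flows from a presynaptic
to a postsynaptic cell. In the developing *C. elegans* brain, reconstructed
at several larval ages, the number of cells grows modestly while the number
of connections grows several-fold, and the network-average asymmetry
between in-degrees and out-degrees, `<alpha>`, rises with age. wormnet
implements (i) the structural statistics used to characterize such
networks, (ii) the randomized null ensembles those statistics are compared
against, and (iii) a minimal network-evolution model that reproduces the
in/out asymmetry and the observed degree-distribution shapes.

## The evolution model

The model keeps the node count fixed: `n` nodes exist from the start,
all isolated. At each time step, one of two things happens:

1. with probability `p` (`p < 0.5`), one existing edge, chosen uniformly
   at random, is removed (a no-op if the network has no edges yet);
2. with probability `1 - p`, one new directed edge is added. Its source
   `i` is drawn with probability proportional to `k_i_out + b` and its
   target `j`, independently, with probability proportional to
   `k_j_in + a`.

`a` and `b` are the *initial attractiveness* of in- and out-degrees: the
additive offsets that give degree-zero nodes a nonzero chance of being
picked, exactly as in classical preferential attachment with initial
attractiveness, but split by direction. The run stops the first time the
edge count reaches `m`, so the result is a simple directed graph with
exactly `n` nodes and `m` edges — comparable to a connectome with the same
counts. Unequal attractiveness (`a != b`) is the model's only source of
in/out asymmetry: `a > b` biases `<alpha>` positive, `a < b` negative, and
`a = b` gives `<alpha>` centred on zero.

Three details of the step process are underdetermined by the verbal model
description, and we fixed them as follows:

* **Self-loops and duplicates.** The drawn (source, target) pair is
  rejected as a whole and redrawn when it would create a self-loop or
  duplicate an existing edge (the alternative — resampling only the
  target — changes the conditional attachment law; whole-pair rejection
  is the minimal reading). After 10^4 consecutive rejections the
  simulator declares saturation and errors rather than spinning.
* **Removal at `E = 0`.** The removal branch needs an edge; when there is
  none the step is a no-op but time still advances, keeping the process
  well defined at startup.
* **Termination.** The run stops at `E = m` exactly, rather than at a
  fixed horizon with `E` near its expectation `(1 - 2p) t`; exactness of
  `m` is what makes model networks directly comparable to a reference
  network's edge count.

`a` and `b` are real-valued and tuned continuously when matching a
reference network; `p` defaults to 0.1 throughout the packaged
experiments.

## Continuum theory

Treating the expected in-degree of a node as a continuous function of
time gives the rate equation

```
dk/dt = (1 - p) (k + a) / ((1 - 2p) t + n a)  -  p / ((1 - 2p) t)
```

with the mean-field substitutions `sum_j k_j_in + a = (1 - 2p) t + n a`
and `E(t) = (1 - 2p) t`, and initial condition `k(t_i) = 1` for a node
that gained its first in-edge at `t_i`. `integrate_rate_equation()`
solves this with `deSolve::ode()` (lsoda, `rtol = 1e-9`, `atol = 1e-10`);
the general closed form involves an unevaluated integral and is not
implemented symbolically. In the `p -> 0` limit the equation integrates
to the closed form of `expected_indegree_smallp()`,
`k(t) = (1 + a)(n a + t)/(n a + t_i) - a`, which the test suite checks
against the ODE to 1e-3 relative accuracy.

Two approximations in this theory matter when validating it against
simulation:

* The removal term is written `-p/E` — the loss rate of an *average*
  in-edge — rather than the per-node rate `-p k_i_in / E`. At the small
  removal probabilities where the theory is exercised (`p = 0.01`) the
  difference is far below Monte-Carlo resolution.
* The theory ignores the simple-graph constraint. When a run approaches
  ~10% density, duplicate-pair rejection measurably suppresses the growth
  of high-in-degree nodes below the ODE curve. The packaged recovery
  check therefore runs in the sparse regime (`n = 300`, 1000 steps,
  ~1% density, 200 realizations, checkpoints every 100 steps, tracking
  the node that received the first in-edge), where the assumptions of the
  rate equation actually hold; at those conditions the ensemble mean sits
  within the 3-standard-error band of the ODE at every checkpoint.

## Structural metrics

All metrics treat the graph as unweighted (synapse counts are carried as
edge weights on input but never enter Eqs for density, paths, clustering,
degrees, or asymmetry).

* **Density** `rho = m / (n (n - 1))` and **mean degree** `m / n` (equal
  for in- and out-degrees by the handshake identity).
* **Average shortest path length** uses directed paths. Connectomes are
  not strongly connected (sensory cells have only out-edges), so the
  strict `n (n - 1)` divisor would be infinite. The default
  `pair_policy = "reachable_only"` averages over ordered pairs joined by
  a directed path; `"all_pairs"` keeps the strict divisor over finite
  distances, and `"require_connected"` refuses disconnected input. The
  flag records a genuine ambiguity in how published path lengths on
  disconnected networks are computed rather than resolving it.
* **Clustering** defaults to the directed coefficient of Fagiolo (2007):
  the realized fraction of all directed triangle configurations through a
  node, `C_i = (A + A^T)^3_ii / (2 (d_i (d_i - 1) - 2 d_i^bidir))`. Two
  properties make it the right default here: it is the definition
  computed by the standard network-analysis stacks for directed graphs,
  and its Erdős–Rényi average converges to the density `rho`, which is
  what published small-world tables for these networks show for their ER
  null columns (and what the packaged convergence test asserts). The
  textbook undirected formula applied to the undirected projection is
  available as `mode = "undirected"`; note it converges to roughly
  `2 rho` on directed ER graphs, so the two modes are not interchangeable
  inside the small-world ratio.
* **Asymmetry index** `alpha_i = (k_in - k_out) / (k_in + k_out)`,
  averaged over nodes. `alpha` is a 0/0 for isolated nodes; the default
  `zero_policy = "skip"` drops them from the average (adjusting the
  divisor), `"count_as_zero"` treats them as symmetric. Toy stars make
  the difference visible; connectome-scale graphs rarely contain isolated
  cells.
* **Small-worldness** `S = (<C>/C_rand) / (L/L_rand)` with `C_rand`,
  `L_rand` from [null_ensemble_stats()]. `S > 1` means excess clustering
  at comparable path length. The graph and its nulls must be measured
  under the same `pair_policy` and clustering mode; the package threads
  both flags through every layer for that reason.

## Null models

* **Erdős–Rényi**: `m` distinct ordered non-loop pairs drawn uniformly
  (exact edge count by construction, via igraph's G(n,m) sampler).
* **Degree-preserving randomization**: directed double-edge swaps —
  `(u1, v1), (u2, v2) -> (u1, v2), (u2, v1)` — rejecting any candidate
  that would create a self-loop or duplicate. "Well randomized" is
  quantified as `swap_factor = 10` successful swaps per edge, the common
  default for double-edge-swap mixing; the factor is exposed. A budget of
  100 attempts per requested swap guarantees termination on swap-rigid
  graphs (a directed 3-cycle admits no legal swap at all), which return
  with a warning instead of hanging.

Ensemble statistics derive per-replicate seeds from one master seed, so
`null_ensemble_stats()` is bit-reproducible, and report standard errors
alongside the means.

## Seeding and determinism

Every stochastic entry point takes an explicit integer seed and restores
the caller's RNG state (via `withr::with_seed()`). Multi-replicate
drivers draw their per-replicate seeds from the master seed in one block,
so results are invariant to evaluation order and rerunning any experiment
with the same arguments is bit-identical. Seeds are kept below 2^31 - 1.

## What the toy generator emulates — and what it does not

`make_toy_connectome()` produces fixtures whose metrics are
hand-computable: directed stars (extreme asymmetry, `<alpha> = -0.5` for
a 4-node in-star), rings (closed-form path length `n/2` as `n` grows),
and a seeded `two_stage` layered feedforward graph mimicking
sensory → interneuron → motor wiring, with pure-source and pure-sink
nodes, occasional skip connections creating triangles, and every motor
cell guaranteed at least one input. These capture the *directionality*
features that stress the metrics (disconnectedness, zero in- or
out-degrees, reciprocal edges) but none of the biology: no cell types, no
synapse-count heterogeneity, no spatial structure, no developmental
correlation between snapshots. Passing tests on these fixtures therefore
validates the arithmetic of the toolkit, not any claim about real
connectomes; real analyses should start from connectivity-matrix exports
read with `read_edge_table()`.

## Problem sizes in the packaged checks

The simulation studies packaged as tests use the model at `n = 300`,
`m = 3000`, `p = 0.1` — the scale at which the asymmetry sweeps and
degree-distribution regimes are conventionally shown — with ensembles of
100 realizations (60 for the secondary tilt check), and the continuum
recovery at `n = 300` over 1000 steps with 200 realizations. Property
suites (metric-oracle equivalence, swap conservation, normalization)
sample graphs of at most 8–15 nodes where brute-force enumeration is
exact. These sizes are the package's own choices for routine runs; all
drivers scale to larger ensembles by changing `replicates`.

## Known limitations

* The model fixes the node set; real connectomes add cells between ages
  (~17% from birth to adulthood). Node growth is out of the model's
  scope by design.
* A single `(a, b)` pair applies to all nodes. Real networks mix cell
  classes with very different wiring propensities — most sensory neurons
  have no in-edges at all — which a homogeneous model cannot hold; the
  `match_connectome()` comparison makes that visible as a large
  zero-degree discrepancy rather than hiding it.
* No estimation procedure for `(a, b)` from a reference network is
  provided; matching is by forward simulation at user-chosen values, and
  the reported total-variation distances are descriptive, not a fit
  criterion.
* Metrics are unweighted; synapse-count-weighted generalizations are not
  implemented.
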