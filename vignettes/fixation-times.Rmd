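---
title: "Fixation probability and fixation time of the Moran Birth-death process on directed graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixation probability and fixation time of the Moran Birth-death process on directed graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moranbd)
```

## The model

A population of `N` individuals occupies the nodes of a strongly connected
directed graph `G = (V, E)`. Residents have fitness 1; mutants have
relative fitness `r` (the interesting regime is `r >= 1`; smaller values
are accepted with a warning). One step of the Moran **Birth-death (Bd)**
process:

1. *Birth*: pick a parent with probability proportional to fitness over
   the whole population (total fitness `r|S| + (N - |S|)` when the mutant
   set is `S`).
2. *death*: pick one of the parent's out-neighbors uniformly at random.
3. *update*: the neighbor becomes a copy of the parent.

The mutant configuration `S` performs an absorbing Markov chain on the
`2^N` subsets of `V`; strong connectivity guarantees absorption at the
empty set (extinction) or at `V` (fixation). The quantities the package
computes, all in steps of this discrete chain (lazy steps, where like
replaces like, are counted; `count_lazy = FALSE` switches to the embedded
jump chain):

* fixation probability `fp_r(G, S)`,
* absorption time `AT_r(G, S)` (unconditional expectation),
* fixation time `T_r(G, S)` (conditioned on fixation) and extinction time
  `ExtT_r(G, S)` (conditioned on extinction), linked by
  `AT = fp * T + (1 - fp) * ExtT`,
* `T_r(G) = max_{S != 0} T_r(G, S)` and the neutral quantities
  `fp^(i) = fp_{r=1}(G, {v_i})`, `fp_min = min_i fp^(i)`.

`solve_exact()` builds the sparse one-step transition matrix row-wise in
compiled code (state = bitmask) and solves the four linear systems with a
direct method — dense below 2^10 states, sparse LU (Matrix) up to the
capacity guard of `N = 14`. Conditional times are obtained from the
conditioned-chain systems for `h = fp * T` and `e = (1 - fp) * ExtT`, and
reported as `NA` where the conditioning event has probability zero. A
fitness of exactly `r = 1` makes `fp` additive over `S`, which collapses
the `2^N` system to the `N`-equation stationarity system solved by
`neutral_fp_vector()`.

## Fixation-time upper bounds

Four efficiently computable upper bounds (in process steps) are exposed,
each with its preconditions reported rather than silently assumed:

| theorem | preconditions | bound on `T_r(G)` |
|---|---|---|
| `bound_theorem1` | `r >= N^2` | `3 N^3` (and `AT <= 2 N^3`) |
| `bound_theorem2` | Eulerian, `r > Delta/delta` | `((1+eps)(2+eps)/eps^2) N^3` with `eps = r delta/Delta - 1` |
| `bound_theorem3` | `r >= 1` | `N^6 / fp_min^4` |
| `bound_theorem4` | balanced, `r >= 1` | `N^14` |

The Theorem-2 slack is fixed at its maximal admissible value because the
bound is monotone decreasing in `eps`; an override argument exists for
reproducing intermediate values. When `fp_min` underflows double
precision the Theorem-3 bound is reported as `+Inf` with a warning rather
than a garbage float. `best_bound()` evaluates all four and returns the
smallest finite fixation-time bound with a full audit trail. The test
suite checks soundness exhaustively: over every strongly connected
digraph on up to 5 nodes (1 + 5 + 83 + 5048 isomorphism classes) and
`r` in {1, 1.1, 2, 25}, the exact `T_r(G)` and maximal absorption time
never exceed any applicable bound.

## Balanced graphs

A graph is *balanced* when at every node the reciprocal-average outdegree
of its predecessors equals the reciprocal-average indegree of its
successors:

```
(1/deg^-(v)) * sum_{u->v} 1/deg^+(u)  =  (1/deg^+(v)) * sum_{v->w} 1/deg^-(w).
```

Equivalently, the edge weight `z(u -> v) = 1/(deg^+(u) deg^-(v))` is a
circulation (conserved at every node). `is_balanced()` evaluates the
equality in exact rational arithmetic — integer numerators and
denominators reduced at each addition — so there is no tolerance knob and
no floating-point false positive; degrees are small integers, so the
arithmetic stays far inside the exactly-representable double range. On
balanced graphs the neutral fixation probability has the closed form
`fp_{r=1}(G, {u}) = (1/deg^-(u)) / sum_v 1/deg^-(v) >= 1/N^2`
(`balanced_fp_formula()`), which the tests confirm against the full
`2^N`-state solve on every balanced graph of up to 5 nodes.

**A caution on named amplifier families.** Undirected graphs, regular
graphs, vortex graphs (`graph_vortex()`) and cyclic complete multipartite
graphs are balanced; the test suite asserts this. For three other
families often described as balanced, the canonical wirings are *not*:

* the superstar (center feeding `l` reservoirs of `m` nodes, chains back
  to the center) violates the equality at every reservoir node whenever
  `l >= 2` — the incoming share is `1/(l m)` but the outgoing share is
  `1/m`, and no local rewiring of that layout fixes it;
* the metafunnel violates it at the outermost layer whenever its depth
  exceeds 1, for the same structural reason;
* the oriented fan with hub `h` and blades `h -> a_i -> b_i -> h`
  (`graph_fan()`, the only layout consistent with the family's usual
  node/edge counts `N = 2k + 1`, `3k`) violates it at every `a_i` for
  `k >= 2`.

These are exact statements about the package's generators, verified by
the rational-arithmetic predicate and by comparing `neutral_fp_vector()`
with the closed form. Single-lobe superstars and depth-1 metafunnels are
balanced, and those cases are what the property tests assert.

## Monte Carlo simulation and the sampling plan

`estimate()` aggregates independent compiled trajectories from one seeded
RNG stream; identical seed and inputs give bit-identical output. Censored
runs (those hitting `step_cap`) are excluded from `fp_hat` by default:
stopping simulations mid-way over-represents trajectories that quickly go
extinct, so treating censored runs as extinctions biases the estimate
downward (that conservative convention is available behind
`censored_as_extinct = TRUE`). Birth selection is O(1) per step via
mutant/resident index lists; a 95% normal interval is attached to
`fp_hat` and t-intervals to the mean times.

`fpras_sample_plan()` turns a finite fixation-time bound into a
guaranteed-accuracy plan: Hoeffding's inequality sets
`n_runs = ceil(log(2/delta) / (2 eps^2))` and Markov's inequality applied
to the best available expected-time bound `B` sets
`step_cap = ceil(2 B n_runs / delta)`, so all runs finish uncensored with
probability at least `1 - delta/2` and `|fp_hat - fp| <= eps` holds with
probability at least `1 - delta`. On balanced graphs a finite `B` exists
for every `r >= 1`, making the scheme fully polynomial; `relative_error`
mode divides the target by the `1/N^2` lower bound on balanced-graph
fixation probabilities. The constants are the standard Hoeffding/Markov
ones and are deliberately conservative.

## Enumeration and the computational experiments

`enumerate_strongly_connected(n)` iterates all `2^(n(n-1))` labeled
digraphs in compiled code, filters by strong connectivity (bitset
reachability), and canonicalizes by minimizing the adjacency bit-string
over all `n!` node permutations. It reproduces the known counts 1, 5, 83,
5048 for `n = 2..5`; the 3-node count is cross-checked in the tests by an
independent igraph-based brute force, and 4-node representatives are
verified pairwise non-isomorphic. `n = 6` (about 10^9 masks) is allowed
behind an `expensive` flag and is hours-scale; it is never exercised by
the tests.

**Stochastic slowdown census.** `monotonicity_census()` computes, for
each graph and each single-mutant start, the exact conditional fixation
time along the grid `r = 1.000, 1.005, ..., 1.300` and flags a pair when
some grid value exceeds the neutral value by more than a relative 1e-9.
The grid step resolves the sharpest known peak (the 4-node star's, at
`r = 1.023`); the criterion and grid are recorded in the output
attributes. On the 83 four-node graphs the package finds **167 of 332**
pairs increasing. This count is robust: it is unchanged under grid
halving, a 5e-4 grid near `r = 1`, a zero tolerance, a
derivative-at-`r=1` criterion, a local-increase-anywhere criterion, and a
widened range `r` in [1, 5]; counting absorption time instead
gives a far larger count and counting only active (configuration-
changing) steps a far smaller one, so neither matches the definition
used here. A commonly cited figure for this census is 182; the package
reports what its exact solver computes, and the solver is itself
validated against closed forms, an independent dense linear-algebra
route, and Monte Carlo on directed fixtures. One detail
the census surfaced: *all four* starting nodes of the 4-node star show
the slowdown — the three leaves peak at `r = 1.023` and the center peaks
near `r = 1.10`.

**Landscape scan.** `landscape_scan()` evaluates, for every 5-node class,
the single-mutant fixation probability and fixation time under uniform
initialization. The fixation time of the uniform mixture is
fixation-weighted by default, `t = sum_v fp_v T_v / sum_v fp_v`, which is
the expected conditional fixation time when the start node is drawn
uniformly and the process is conditioned on fixation; the unweighted mean
of `T_v` is available since the convention is not canonical. Under both
conventions and at both `r = 1.1` and `r = 2`, the slowest graph is the
undirected star `S_5`. Among oriented graphs (no reciprocated edges) the
slowest is the cyclic complete tripartite graph with parts (1, 1, 3) — a
fan of triangles sharing one hub edge, and a balanced graph — rather than
the hub-and-blade fan `F_5`, which ranks 8th of the 76 oriented classes.

**Scaling experiments.** `family_scaling()` simulates seeded uniform
single-mutant trajectories on fan and vortex graphs across sizes and fits
a log-log slope of mean fixation time against `N`. At desk scale
(`k = 2..20`, 1000 runs per cell) the fitted slopes come out near 3 at
`r = 1.1` and near 2.5 at `r = 100` — growth that is unambiguously
polynomial and of low degree, though steeper than an exact `N^2` over
these sizes (the local log-log slope still decreases with size at the
largest `k` tested).
The four-column graph (`graph_four_column()`) shows the opposite regime
contrast: from the left-half configuration its exact fixation time at
`r = 1.1` is several times the `r = 100` value already at `N = 8`, and
the ratio widens with size, while the strong-selection time stays well
inside the `3 N^3` bound.

## Generator wiring choices

Figure-derived families required explicit wiring decisions, frozen as
follows:

* `graph_four_column(k)`: four vertical two-way paths of `k` nodes;
  two-way rows joining the middle columns; the side columns attach to
  their middle column two-way in the bottom row (which makes the graph
  strongly connected) and by one-way side-to-middle edges in all higher
  rows, creating the mutual one-way pressure that slows fixation at small
  `r`. The `k = 4` edge set is frozen as a plain-text fixture so the
  generator cannot drift silently.
* `graph_fan(k)`: hub plus `k` blade pairs `h -> a_i -> b_i -> h`
  (`N = 2k + 1`, `3k` edges).
* `graph_vortex(k)`: two relay nodes and two `k`-batches in the one-way
  circulation `s -> A -> t -> B -> s` (`N = 2k + 2`, `4k` edges;
  balanced).
* `graph_lollipop()`: undirected triangle with an undirected pendant
  edge.

## Numerical choices and limitations

* Cross-check tolerance is 1e-10 relative throughout the tests; the
  direct solves on <= 2^14 states are far more accurate than that.
* The neutral `N`-equation system is solved by least squares on the
  stationarity equations plus the normalization row (`qr.solve`), which
  is robust to the one-dimensional kernel.
* The star-peak search uses a 61-point grid plus golden-section
  refinement to width 1e-5; unimodality on the bracket is checked
  empirically by the grid.
* Problem sizes used by the shipped tests and the acceptance script:
  exact solves up to `N = 12`, exhaustive scans over all 5048 five-node
  classes, simulations of 300-100000 runs on graphs up to `N = 45`.
  These sizes were chosen so the whole suite runs in minutes on one CPU.
* The synthetic fixtures (seeded random strongly connected / Eulerian /
  undirected / circulant digraphs) exercise structural variety at small
  `N`; they do not emulate degree heterogeneity or modularity of large
  real interaction networks, so passing tests certify the solvers and
  bounds, not any claim about empirical networks.
* Death-Birth updating, weighted or multi-edges, self-loops, and `n >= 7`
  enumeration are out of scope.
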