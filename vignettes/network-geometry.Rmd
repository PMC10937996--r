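---
title: "Network entropy, Forman-Ricci curvature and normalised Ricci flow on expression-weighted interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network entropy, Forman-Ricci curvature and normalised Ricci flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riccinet)
```

## The model

`riccinet` treats a cell's signalling state as a random walk on a
protein-interaction network (PIN) weighted by that cell's transcriptome.
Let `G = (V, E)` be the undirected PIN with adjacency `A` and let `x > 0`
be transcript abundance matched to the nodes. The mass-action principle
sets the propensity of an interaction proportional to the product of its
endpoints' abundances, giving the weighted network `W(x) = (a_ij x_i x_j)`
and the transition matrix

$$p_{ij} = \frac{a_{ij} x_j}{\sum_k a_{ik} x_k}.$$

Because the chain is reversible on a connected graph, its stationary
distribution is available in closed form as relative node strength,
`π_i ∝ x_i (Ax)_i`, which the package uses directly (and verifies against
`πP = π`).

Three quantities are built on this walk:

**Network entropy** is the walk's entropy rate
`S_R = Σ_i π_i S_i` with `S_i = −Σ_k p_ik log p_ik` (nats; `p log p := 0`
at `p = 0`). It is scale-invariant in `x` and, when reported as a
normalised value, is divided by the maximal rate the topology admits,
`log λ_max(A)` — the spectral-radius convention inherited from the
signalling-entropy literature; the package documents this as a convention
rather than a derived result. High entropy characterises promiscuous,
stem-like signalling.

**Forman-Ricci curvature** on an edge, with node weights `W_i = 1/deg(i)`
and edge weights `ω_ij = 1/(x_i x_j)` (reciprocal co-expression: strongly
co-expressed neighbours are "close"):

$$R_F(i,j) = \frac{1}{\deg i}\Big[1 - \sum_{k \in N(i)\setminus j}
\sqrt{x_k/x_j}\Big] + \frac{1}{\deg j}\Big[1 -
\sum_{k \in N(j)\setminus i}\sqrt{x_k/x_i}\Big].$$

The `1/deg` node weights bound both brackets independently of degree, so
nodal means `Ric_i` (average over incident edges) and the total
`Ric(x) = Σ_i π_i Ric_i` do not correlate with entropy merely through a
shared degree dependence. Curvature is monotone decreasing in an edge's own
distance (`∂R_F/∂ω_ij < 0`), the property that makes the flow below
contractive toward its target.

A note on the printed closed forms for the k-star (below): assembling the
leaf's nodal curvature from the per-edge half-terms gives
`R_F(l) = 1 + (3 − k − √ε)/k`; the package's `star_total_curvature()` uses
this form, which agrees with the general pipeline to machine precision on
every `(k, ε)` tested (the equivalence is an acceptance-level test).

**Normalised discrete Ricci flow** interpolates between two measured
states. With distances initialised on the start state as
`d_0 = 1/(x_i x_j)` and the normaliser `R̄ic` fixed to the end state's
curvature field, each iteration applies

$$d_{t+\Delta t} = d_t + \Delta t\,(R_F^t - \bar{Ric})\,d_t,$$

recomputing `R_F^t` from the current distances through the general weighted
Forman form (after one step `d` is no longer of product form; node weights
stay fixed at `1/deg`, which is also what makes the iteration well-posed —
the flow only supplies update equations for edge quantities). Each point of
the trajectory yields a predicted weighted network `W_p = 1/d_t`, directly
comparable to measured intermediate samples.

## Parameters that matter

- **Step size `Δt`** (unitless). Too large and a distance can be driven
  nonpositive; too small and convergence needs many iterations. By default
  the package selects, by one-step simulation from the start state, the
  largest value on a linear grid `0.001–0.1` (step `0.001`) that keeps all
  first-step distances positive; the grid's span is the range considered in
  practice for PIN-scale flows and its resolution is fine enough to contain
  any interior optimum. The theoretical first-step bound
  `Δt* = min_{E^*} 1/(R̄ic − R_F^0)` (over edges where the target exceeds
  the initial curvature; `+∞` if none) is always reported alongside.
  One caveat the package makes explicit: one-step positivity does not
  guarantee positivity at later iterations. Under extreme rewiring
  (per-gene fold changes of several log-units on heavy-tailed expression)
  curvature gaps can grow mid-flow and a step can fault; `run_flow()` then
  raises an error naming the iteration and the current bound, rather than
  silently clamping.
- **Iteration count** (default 150). Chosen as "comfortably past
  convergence" for the step sizes above rather than as a stopping rule; no
  early stopping is applied by default, and the per-iteration residual
  `max_E |R_F^t − R̄ic|` is recorded so users can judge convergence
  themselves (both the per-edge maximum and, via the stored fields, any
  aggregate a user prefers).
- **Pseudocount** (default 0). Matching requires `x > 0`. Zero expression
  is a hard error by default — normalised counts of exactly zero carry no
  mass-action signal and silently imputing one would fabricate edges'
  weights; an explicit pseudocount can be supplied when the user decides
  that is appropriate for their normalisation.
- **`record_every`** thins trajectory storage for large graphs; iteration 0
  and the final iteration are always kept.

## The k-star toy model and the two signalling regimes

The analytically tractable fixture is the k-star: a hub `i` with `k`
leaves, all weights 1 except one distinguished leaf `j` with weight
`ε > 0`. Closed forms for `S_R`, the stationary distribution (the hub holds
probability 1/2 for every `k` and `ε`) and total curvature are implemented
in `star_entropy()`, `star_stationary()` and `star_total_curvature()`, and
the acceptance tests pin the general sparse pipeline to them at `1e-10`
across the full `(k, ε)` grid.

Entropy peaks at `ε = 1` for every `k`. Entropy can be lowered either by
`ε < 1` (favouring the `k−1` plain leaves, "many for one") or by `ε > 1`
(favouring `j`, "one for many"). For `k = 2` curvature also peaks at
`ε = 1` and the two measures always move together; for every `k ≥ 3` there
is an `ε`-range above 1 where entropy falls while curvature still rises —
the two-regime result. `regime_scan()` evaluates both closed forms on a
dense grid (`ε ∈ [0.01, 10]`, step `0.001` — covering the qualitative range
of interest with a crisp boundary) and classifies the local association by
the sign of the product of grid derivatives rather than by windowed Pearson
correlations, which would blur the regime boundary. `anticorrelated_range()`
reports, per `k`, the extent of the opposed-sign region above `ε = 1`; on
the scan grid it is empty for `k = 2` and widens monotonically with `k`
(saturating at the grid's upper edge for larger `k`).

## What the synthetic data emulate — and what they do not

`make_star()` builds the toy network. `make_random_pin()` emulates a
desk-scale interactome: the largest component of a sparse Erdős–Rényi
graph with a target mean degree (default 4) and log-normal expression
(`sdlog = 0.5`, a realistic dispersion for normalised abundance).
`make_timecourse()` produces time-ordered truths between two states in two
ways: sampled from the flow trajectory itself (for self-consistency tests)
or from the elementwise log-linear path `W_s = W_0^{1-s} W_T^s` (a curved
path generated independently of the flow, for non-circular ordering tests),
with optional multiplicative log-normal noise.

These generators deliberately omit much of real single-cell data: no
dropout, no library-size variation, no count discreteness, no correlated
gene programmes, and random rather than scale-free topology. Passing tests
therefore demonstrate the correctness and internal consistency of the
machinery — closed-form agreement, convergence, ordering recovery under
noise — not that the flow will order any particular biological time course.

One empirical finding from building the ordering tests deserves record. On
truths lying on a *per-edge monotone* path (such as the geometric
interpolation), the straight-line null is close to unbeatable: projecting
onto the chord filters transverse curvature and preserves the ordering
almost perfectly. The flow also orders such truths well (the suite asserts
high positive correlation), but its time parametrisation is exponential
rather than uniform — and since curvature is invariant under a global
rescaling of `d`, the flow's endpoint can differ from the end state's
weights by a scale factor — so its closest-pass/time relation is slightly
less linear than the chord's. The regime where the flow demonstrably beats
the straight line is on genuinely curved paths, i.e. truths from the flow
family itself (the suite's comparison test, where the null sometimes
collapses all closest passes to a single iteration and loses all ordering
power). Discriminating the two on real data relies on real rewiring being
far from per-edge monotone interpolation.

## Numerical choices

- Stationary distributions use the closed strength form, not an eigensolve;
  an independent lazy-walk power iteration serves as the test oracle.
- The adjacency spectral radius (for the maximal entropy rate) is computed
  by power iteration on `A + I`; the shift makes the dominant eigenvalue
  strictly separated even on bipartite topologies (stars, trees), where
  plain power iteration oscillates.
- Curvature has two code paths — the expression form and the
  general-distance form — kept deliberately separate and cross-checked to
  `1e-10` on random fixtures; the flow uses only the distance form.
- Closest-pass ties are broken toward the earliest iteration; distances are
  L2 over unique undirected edges (the full-matrix metric is `√2` times
  larger, a monotone rescaling that cannot change any argmin).
- Ordering correlations are reported both over intermediate time points
  only (the primary statistic) and including the final point, which by
  construction sits at the last iteration; neither is treated as canonical.
- Degenerate correlation inputs (fewer than 3 points, zero variance in
  closest passes) yield `NA` rather than an arbitrary number.
- The linear null trajectory pins its endpoint to `W_T` bitwise; floating
  increments need not land there exactly.

## Limitations

- Node expression cannot be reconstructed from flow distances: only
  `W = 1/d` is defined along the trajectory, and no node-level
  factorisation is claimed.
- The flow requires identical topology at both ends; differential network
  structure (edge gain/loss) is out of scope.
- Directed and signed networks are unsupported; Ollivier-Ricci curvature
  and triangle-aware augmented Forman variants are out of scope.
- The problem sizes exercised in the test suite (stars to `k = 20`, random
  networks up to 100 nodes, 150 flow iterations, 10-seed replicates) are
  desk-scale choices; the sparse implementation itself is linear in edges
  per flow iteration and has no such limits built in.
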