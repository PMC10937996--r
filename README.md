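# riccinet

Differential-geometry tools for biological network rewiring. `riccinet` is
for computational biologists who study cellular differentiation (or its
failure in cancer) through protein-interaction networks (PINs) weighted by
transcriptomic profiles, and who want, beyond snapshot statistics, a way to
*interpolate* the rewiring between two measured states.

## What it computes

Given an undirected PIN with adjacency `A = (a_ij)` and a strictly positive
expression vector `x` matched to its nodes:

- **Mass-action weighting.** `W(x) = (a_ij x_i x_j)` and the random-walk
  transition matrix `p_ij = a_ij x_j / Σ_k a_ik x_k`, whose stationary
  distribution has the closed form `π_i = x_i (A x)_i / Σ_kj a_kj x_k x_j`.
- **Network entropy.** Local entropies `S_i = −Σ_k p_ik log p_ik` and the
  entropy rate `S_R = Σ_i π_i S_i`, optionally normalised by the topology's
  maximal rate `log λ_max(A)`. High `S_R` marks promiscuous, stem-like
  signalling.
- **Forman-Ricci curvature.** On each edge, with node weights `1/deg` and
  edge weights `ω_ij = 1/(x_i x_j)`,

  `R_F(i,j) = deg(i)⁻¹ [1 − Σ_{k∈N(i)∖j} √(x_k/x_j)] + deg(j)⁻¹ [1 − Σ_{k∈N(j)∖i} √(x_k/x_i)]`,

  plus nodal means and the stationary-weighted total `Ric(x) = Σ_i π_i Ric_i`.
  Entropy and total curvature correlate positively in promiscuous ("many for
  one") regimes but can anticorrelate in committed ("one for many") regimes —
  the package's k-star closed forms and regime scans make this two-regime
  behaviour explicit.
- **Normalised discrete Ricci flow.** Starting from distances
  `d_0 = 1/(x_i x_j)` on the start state, iterate
  `d_{t+Δt} = d_t + Δt (R_F^t − R̄ic) d_t`, where the normaliser `R̄ic` is the
  end state's curvature field. Step size is chosen empirically (largest grid
  value keeping first-step distances positive) with the theoretical bound
  `Δt* = min 1/(R̄ic − R_F^0)` over edges where the gap is positive. Each
  trajectory point yields a predicted weighted network `W_p = 1/d_t`.
- **Trajectory evaluation.** Closest-pass ordering of true intermediate
  samples along a trajectory (Euclidean distance over edges, argmin per
  sample), Pearson tests of recovered-vs-true ordering, a straight-line null
  trajectory, and Fisher-z comparison of correlations between cohorts.

Synthetic generators (k-stars, random connected expression-weighted graphs,
time courses with known ordering) make every stage testable without any
external data.

## Worked example

A 10-star with all weights 1 is the maximum-entropy state; raising the
distinguished leaf to `ε = 6` ("one for many" signalling) lowers entropy
while *raising* total curvature — the anticorrelated regime:

```r
library(riccinet)
stem <- make_star(10, eps = 1)
diff <- make_star(10, eps = 6)

ent <- network_entropy(stem)
c(S_R = ent$rate, normalised = ent$normalised,
  R_F = network_curvature(stem)$total)
#>        S_R normalised        R_F
#>     1.1513     1.0000     0.2000

ent2 <- network_entropy(diff)
c(S_R = ent2$rate, normalised = ent2$normalised,
  R_F = network_curvature(diff)$total)
#>        S_R normalised        R_F
#>     0.9957     0.8648     0.2244
```

The flow from the first state toward the second converges to the target
curvature field, and recovers the ordering of intermediate states sampled
along the way:

```r
traj <- run_flow(stem, diff)
traj
#> flow_trajectory: 150 iterations, dt = 0.1 (dt* = 1.87766)
#>   residual max|R_F - norm|: 0.5326 (t=0) -> 0.00265 (t=150)

tc <- make_timecourse(stem, diff, c(0.2, 0.5, 0.8), method = "flow")
closest_pass_ordering(traj, tc$truths, tc$times)
#> closest-pass ordering over 150 trajectory points
#>   closest pass: 30, 75, 120
#>   Pearson r = 1.0000 (p = 9.49e-09) on intermediate points
```

The entropy rate `1.1513 = log(10)/2` nats is the 10-star's theoretical
maximum (normalised entropy 1); the residual trace shows the flow ending two
orders of magnitude closer to the target curvature than it started; the
closest passes land exactly at the sampled iterations (30, 75, 120 of 150).

A file-based pipeline (`run_pipeline()`) and a command-line dispatcher
(`inst/cli/riccinet.R`, subcommands `entropy`, `curvature`, `flow`,
`evaluate`, `kstar-scan`, `simulate`, `pipeline`) wrap the same functions
for shell use.

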