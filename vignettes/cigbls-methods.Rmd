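---
title: "CI-GBLS: model, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CI-GBLS: model, numerics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cigbls)
```

## 1. The modelling problem

A fed-batch fermentation soft sensor predicts a slowly drifting quality
variable (product concentration, assayed every 12 h with a ~4 h analytical
delay) from process variables logged every 12 min. The estimator in this
package is a *broad* network: instead of stacking layers, it widens a flat
layer of randomly mapped feature nodes and nonlinear enhancement nodes, all
connected linearly to the output, and trains by one regularized linear
solve. Three ingredients distinguish CI-GBLS from a plain broad learning
system (BLS):

* **Channel independence (CI).** Each input variable owns an isolated
  feature channel `Z_i = φ(x_i W_i + b_i)`. A fully connected random map
  forces all variables into one shared parameter space, which mixes
  heterogeneous dynamics and propagates noise across variables; isolation
  extracts per-variable temporal features and leaves cross-variable
  coupling entirely to the shared output weights `W` (the prediction
  `Ŷ = AW` is a linear span over the decoupled bases). With linear `φ`,
  each channel block has effective rank 2 (`x_i` and the constant), so the
  model's nonlinearity comes from the enhancement layer; the overall model
  class is additive across channels — interactions appear only through the
  output-layer recombination. This is a deliberate bias, not an accident:
  it is what reduces overfitting on limited, noisy batches.
* **Anchored RBF enhancement.** Enhancement nodes are
  `exp(−γ‖z − u‖²)` distances to per-channel K-Means anchors rather than
  random projections, giving data-adaptive nonlinear bumps along each
  channel's feature manifold. The total number of anchors equals the total
  number of enhancement nodes.
* **Anchor-graph manifold regularization.** Samples close on the data
  manifold should receive close predictions. The usual graph-Laplacian
  penalty needs an `N×N` neighbour graph (`O(N²)`); here the anchor
  affinities already computed for the enhancement layer are reused:
  row-normalize `H` to `H̄`, set `Δ_kk = Σ_j H̄_jk`, and use the low-rank
  row-stochastic similarity `Ŝ = H̄Δ⁻¹H̄ᵀ` with random-walk Laplacian
  `L = I − Ŝ`. The penalty quadratic form collapses to
  `AᵀLA = AᵀA − (AᵀH̄)Δ⁻¹(H̄ᵀA)`, which needs only `N×m` products, and the
  solution stays closed-form:
  `((1+β)AᵀA − β(AᵀH̄)Δ⁻¹(H̄ᵀA) + λI)W = AᵀY`.

When `β = 0` this is exactly ridge regression on `A`; in the opposite
limit, if the similarity term vanishes (`L = I`) and `λ = 0`, the solution
is the unregularized least-squares weights scaled by `1/(1+β)` — at
`β = 1` the weight norm halves exactly, which is the mechanism behind the
over-smoothing observed for large `β`.

## 2. Tunable parameters

| parameter | meaning | default | rationale |
|---|---|---|---|
| `nodes_per_channel` | feature nodes per variable | 10 | 18 variables × 10 = 180 feature nodes, the reference operating point |
| `anchors_per_channel` | K-Means anchors (= enhancement nodes) per channel | 10 | same budget as feature nodes |
| `gamma` | RBF width (1/length² in scaled feature space) | 0.1 | reference operating point; grid-searchable over `[1e-4, 1]` |
| `lambda_reg` | ridge penalty | 1e-3 | reference operating point; grid-searchable over `[1e-4, 10]` |
| `beta` | manifold strength | 0.05 | flat low-error plateau extends over `[1e-6, ~0.1]`; degradation past 1 |
| `xi_scale` | enhancement-block scaling in `A=[Z|ξH]` | 0.5 | balances the two blocks; fixed, not searched |
| `kmeans_iters` | Lloyd iteration cap | 100 | reproducibility and bounded cost |
| `weight_init_range` | random-map draw interval | [−1, 1] | conventional for random-map networks (the distribution is otherwise unspecified; uniform chosen here) |

All randomness flows from one integer `seed` through deterministic
sub-streams (`sub_seed(master, index)`), one per channel / batch /
restart, so adding a channel never shifts another channel's draws and runs
are bit-reproducible.

## 3. Preprocessing pipeline

* **Assay alignment** (`shift_target`): an assay recorded at `t` reflects
  the broth at `t − delay`; quality timestamps are shifted back by the
  delay (240 min by default, i.e. 20 samples at 12-min sampling). Delays
  that are not a multiple of the sampling interval are rounded with a
  warning; assays shifted before batch start are dropped.
* **Label interpolation** (`interpolate_labels`): linear interpolation
  between assays on the process grid, nearest-value padding outside the
  assay range. Fermentation quality has large inertia, so the
  piecewise-linear trend is a defensible stand-in for unobserved values —
  but it *is* a modelling choice: the supervised targets between assays
  are reconstructions, not measurements.
* **Ordering**: by default shift happens before interpolation
  (`order = "shift_first"` in `build_design`), i.e. assays are moved to
  their draw times and then densified; `"interpolate_first"` densifies the
  raw series then shifts the dense vector. The two differ only near batch
  edges.
* **Windows** (`make_windows`): each row is the flattened `window_len`
  -sample history of all variables ending at `t` (default `window_len = 1`,
  a current-time snapshot). Each lagged column becomes its own independent
  channel downstream; windows never cross batch boundaries. Windowing
  lives entirely in the pipeline — the channel mapper always consumes one
  column per channel.
* **Splits** (`stratified_batch_split`): batch-granularity, stratified by
  control mode, `round(0.8·n)` (half-up) training batches per stratum.
* **Scaling** (`minmax_fit`/`minmax_apply`): per-column min-max fitted on
  training rows only; test values are not clipped. Constant columns map
  to 0 with a warning.
* **Metrics**: RMSE, MAE, and `R² = 1 − SSE/SST` on the test set.

## 4. Numerical choices

* All solves go through Cholesky factorization of the (SPD) normal-equation
  matrix — never an explicit inverse. A numerically rank-deficient system
  (possible at `λ = 0`) falls back to an SVD pseudo-inverse with a warning.
* K-Means: k-means++ initialization, single restart, 100-iteration cap,
  empty clusters re-seeded at the point farthest from its assigned center,
  assignment ties broken by lower index. Channels with fewer distinct
  points than requested anchors get fewer anchors (warning).
* `H̄` is the row-normalization of the *raw* enhancement matrix `H`; the
  `ξ` scaling enters only the state matrix `A`. (Whether normalization
  happens before or after `ξ` is an open choice; since every row of `H`
  would be multiplied by the same `ξ`, row normalization cancels it — the
  choice is therefore cosmetic, and the raw-`H` convention is used.)
* Anchor degrees `Δ_kk` are floored at 1e-12: a dead anchor carries no
  similarity mass and would otherwise divide by zero.
* `Ŝ` is used as built (row-stochastic, not symmetrized); the quadratic
  form `AᵀLA` is assembled exactly as written, and its small asymmetry
  (at round-off level) is irrelevant to the solve.
* The dense kNN-Laplacian oracle (`build_dense_lap_oracle`) exists only
  for verification at small `N`: "or"-rule symmetrized kNN adjacency,
  Gaussian edge weights with `σ` defaulting to the median retained-edge
  distance (no rule is prescribed, so a standard robust default is used),
  `L = D − S`. Equivalence of the reduced-rank path with the densely built
  `L = I − Ŝ` is a tested invariant, as is the trace-form identity
  `Tr(ŶᵀLŶ) = ½ΣS_pq‖ŷ_p−ŷ_q‖²`.
* Feature-node outputs are not normalized before the enhancement mapping
  (no such step is specified anywhere; adding one would change the meaning
  of `γ`).
* No `N×N` object is ever allocated in the production path; the test suite
  asserts this with an allocation profiler at `N = 10⁴` where available.

## 5. What the synthetic generator does — and does not — establish

`simulate_dataset()` emulates the *statistical shape* of an
industrial-penicillin benchmark, not its physics: latent
biomass/substrate/product trajectories from a Monod-type fed-batch model
(logistic growth, substrate-limited and product-inhibited production, so
quality is monotone non-decreasing), three control-mode strata with
different feed policies (stepped recipe, operator adjustments, feedback to
a substrate setpoint), 18 observed channels that are lagged nonlinear
mixtures of the latents with batch-level gain effects, two pure-distractor
channels, relative sensor noise, and a 12-min/12-h/4-h multi-rate assay
geometry. Defaults (90 batches, 230 h, 18 variables, noise 2 % of signal
SD, 5 % batch variability) are fixed once as the package's stated world.

It does **not** reproduce Raman spectra, advanced-process-control
behaviour, faults, or real actuator/sensor dynamics. A green test on this
generator establishes that the estimator recovers a smooth latent quality
variable from heterogeneous, lagged, noisy nonlinear mixtures under
multi-rate supervision and batch-level distribution shift — it does not
certify performance numbers on the real benchmark, whose download is
outside the package's scope.

Scaled-down worlds (9–24 batches, 80–120 h) are used inside the test suite
for budget reasons; the generator's defaults are unchanged. Two empirical
regularities are tested as stochastic invariants on those worlds: the
median-RMSE ablation ordering (full ≤ w/o Graph < w/o CI) and the
`β`-sensitivity shape (flat plateau up to `β ≈ 0.1`, sharp degradation at
`β = 10`). The runtime-scaling check fixes the Lloyd iteration budget,
because the linear-complexity claim is stated for a fixed average
iteration count while adaptive convergence takes more sweeps at larger
`N`.

## 6. Design decisions where the design was open

* Random-map distribution: uniform on `[−1, 1]`, configurable.
* Feature activation defaults to `linear` (the feature map is described as
  a linear random mapping), enhancement is the RBF; the fully connected
  baseline uses `tanh` enhancement nodes.
* Anchors are fitted on training feature nodes only and frozen for
  prediction — the only leakage-safe reading of the training protocol.
* The `w/o CI` ablation keeps the total node and anchor budget (one global
  random map of width `M·k`, global K-Means with `M·m_k` centers) so the
  comparison isolates the wiring, not the capacity.
* Grid-search ties are broken toward smaller `β`, then larger `λ` (prefer
  the less complex model at equal validation RMSE).
* Multi-output targets (`C > 1`) are supported throughout since every
  formula is already matrix-valued, although the fermentation use case
  predicts a single quality attribute.

## 7. Known limitations

* The model is additive across channels by construction; genuinely
  interactive effects (e.g. quality driven by a product of two variables)
  can only be approximated through the output-layer recombination of
  per-channel nonlinearities.
* Linear label interpolation biases the supervised targets between assays;
  errors measured against interpolated labels slightly understate errors
  against the true quality between assay points.
* Min-max scaling with no clipping means unprecedented operating regions
  extrapolate both the linear and the RBF blocks; RBF activations decay to
  0 far from all anchors, so extrapolation degrades toward the linear
  part. Very small training worlds (few short batches) can extrapolate
  badly — the worked example sizes are the practical floor.
* No incremental/online update of the solve or the anchor structure is
  provided; refitting is the intended update path (training is seconds).
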