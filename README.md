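# cigbls

Closed-form soft sensors for multivariate batch processes, built around a
**Channel-Independent anchor-Graph-regularized Broad Learning System
(CI-GBLS)**.

## The problem

In fed-batch fermentation (the motivating case is industrial penicillin
production) the key quality attribute — product concentration — is measured
by offline laboratory assay every ~12 hours, with a ~4 hour analytical
delay, while dozens of process variables (feed rates, temperature, pH,
dissolved oxygen, off-gas analysis, ...) are logged every 12 minutes. A
*soft sensor* is a regression model that predicts the quality variable
online from the cheap high-frequency signals. Deep sequence models can do
this, but their training cost and retraining latency are a poor fit for
drifting industrial processes. This package implements a wide, flat
network whose training is a single linear solve.

## The model

Given inputs `X ∈ R^{N×M}` and targets `Y ∈ R^{N×C}`:

1. **Channel-independent feature nodes.** Each variable `x_i` gets its own
   random affine map, `Z_i = φ(x_i W_i + b_i)`, so channels are physically
   isolated: noise in one variable cannot leak into another's features.
   `Z_f = [Z_1 | … | Z_M]`.
2. **Anchored RBF enhancement nodes.** Per channel, `m_k` anchors `u_{i,k}`
   are found by K-Means (k-means++, capped Lloyd iterations) on that
   channel's feature rows, and enhancement nodes are
   `H_i[j,k] = exp(−γ‖z_{i,j} − u_{i,k}‖²)`. The state matrix is
   `A = [Z_f | ξH]`.
3. **Anchor-graph manifold regularization.** Row-normalizing `H` gives
   `H̄`; with anchor degrees `Δ_kk = Σ_j H̄_jk`, the low-rank, row-stochastic
   similarity `Ŝ = H̄Δ⁻¹H̄ᵀ` defines the random-walk Laplacian `L = I − Ŝ`.
   The output weights minimize

   `‖AW − Y‖² + λ‖W‖² + β·Tr(WᵀAᵀLAW)`

   with the closed-form solution

   `((1+β)AᵀA − β(AᵀH̄)Δ⁻¹(H̄ᵀA) + λI) W = AᵀY`,

   computed through `N×m` products only — no `N×N` matrix is ever formed,
   so training stays linear in the number of samples.

The package also ships the preprocessing pipeline (assay-delay alignment,
linear label interpolation with boundary padding, sliding windows,
stratified batch splits, train-only min-max scaling), a grid-search and
ablation/sensitivity driver, a dense kNN-Laplacian oracle used to verify
the reduced-rank algebra, and a seeded generator of penicillin-like
multi-rate batch data so everything runs without external downloads.

## Worked example

```r
library(cigbls)

cfg   <- sim_config(n_batches = 24, duration_h = 120, n_vars = 18, seed = 11)
ds    <- simulate_dataset(cfg)
split <- stratified_batch_split(ds$ids, ds$modes, train_frac = 0.8, seed = 1)
des   <- build_design(ds, split, delay_minutes = 240)   # 4-h assay delay

fit <- fit_cigbls(des$train$X, as.matrix(des$train$y), cigbls_config(seed = 1))
print(fit)
#> CI-GBLS fit: 180 feature + 180 enhancement nodes (channel-independent)
#>   lambda=0.001 gamma=0.1 beta=0.05 xi=0.5 seed=1
#>   train RMSE 0.2366  MAE 0.183  R2 0.9949  (3.43 s)

pred <- predict(fit, des$test$X)[, 1]
unlist(compute_metrics(des$test$y, pred))
#>      rmse       mae        r2
#> 0.5875508 0.4782789 0.9664579
```

The fit trains 360 nodes on ~11,500 samples in a few seconds and explains
~97 % of the held-out-batch quality variance: RMSE/MAE are in the
concentration units of the simulated product (g/L), and `r2` is the
fraction of test variance explained. `run_ablation()` reproduces the
component analysis (full model vs `w/o Graph` vs `w/o CI` vs `K-BLS`),
and `beta_sensitivity()` sweeps the manifold strength `β`.

A command-line driver is installed with the package:

```sh
cigbls=$(Rscript -e 'cat(system.file("scripts","cigbls",package="cigbls"))')
Rscript $cigbls simulate --out data.csv --seed 1 --n-batches 24 --duration-h 120
Rscript $cigbls fit --data data.csv --seed 1 --out results/
Rscript $cigbls ablate --data data.csv --seed 1 --out results/
Rscript $cigbls sensitivity --data data.csv --beta-grid "1e-6,1e-3,0.1,1,10" --out results/
```

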