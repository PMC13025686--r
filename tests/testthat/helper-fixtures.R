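# Shared fixtures: all built in code, seeded.

# random regression system
rand_system <- function(n, L, C = 1L, seed = 1L) {
  set.seed(seed)
  list(A = matrix(rnorm(n * L), n, L), Y = matrix(rnorm(n * C), n, C))
}

# a small state matrix + enhancement matrix produced by the real CI path
small_ci_state <- function(seed = 1L, n = 30L, M = 3L, k = 4L, m_k = 3L,
                           gamma = 0.5, xi = 0.5) {
  set.seed(seed)
  X <- matrix(runif(n * M), n, M)
  maps <- init_channel_maps(M, k, seed = seed)
  fm <- ci_feature_map(X, maps)
  anchors <- fit_channel_anchors(fm$Z, fm$layout, m_k, gamma, seed = seed)
  enh <- rbf_enhance(fm$Z, fm$layout, anchors)
  A <- assemble_state(fm$Z, enh$H, xi, fm$layout, enh$layout)
  list(X = X, maps = maps, Z = fm$Z, layout = fm$layout, anchors = anchors,
       H = enh$H, h_layout = enh$layout, A = A,
       Y = matrix(rowSums(sin(3 * X)) + rnorm(n, 0, 0.05), n, 1))
}

# small simulated world + train/test designs
small_world <- function(seed, n_batches = 9L, duration_h = 80, n_vars = 10L,
                        train_frac = 0.75) {
  cfg <- sim_config(n_batches = n_batches, duration_h = duration_h,
                    n_vars = n_vars, control_modes = 3L, seed = seed)
  ds <- simulate_dataset(cfg)
  sp <- stratified_batch_split(ds$ids, ds$modes, train_frac, seed = seed)
  des <- build_design(ds, sp, delay_minutes = cfg$assay_delay_h * 60)
  list(cfg = cfg, ds = ds, split = sp, design = des)
}

# ground-truth dense quality aligned to a design side's rows
design_truth <- function(ds, side) {
  vapply(seq_along(side$y), function(i) {
    b <- ds$batches[[side$groups[i]]]
    b$truth$value[match(side$time_min[i], b$truth$time_min)]
  }, 0)
}
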