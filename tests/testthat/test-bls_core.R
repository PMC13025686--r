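test_that("random maps are reproducible, correctly shaped, seed-sensitive", {
  cfg <- bls_config(n_feature_groups = 3L, nodes_per_group = 10L, seed = 42L)
  maps <- init_random_maps(cfg, 18L)
  expect_length(maps, 3L)
  for (m in maps) {
    expect_identical(dim(m$weights), c(18L, 10L))
    expect_length(m$bias, 10L)
    expect_true(all(m$weights >= -1 & m$weights <= 1))
  }
  expect_identical(maps, init_random_maps(cfg, 18L))
  others <- lapply(c(7L, 8L, 9L), function(s)
    init_random_maps(bls_config(n_feature_groups = 3L, nodes_per_group = 10L,
                                seed = s), 18L))
  for (o in others) expect_false(identical(maps, o))
  expect_error(init_random_maps(cfg, 0L), class = "cigbls_invalid_argument")
})

test_that("feature mapping matches identity, bias-only, and loop-oracle cases", {
  cfg <- bls_config(n_feature_groups = 1L, nodes_per_group = 3L,
                    feature_activation = "linear", seed = 1L)
  X <- matrix(rnorm(15), 5, 3)
  id_map <- list(list(weights = diag(3), bias = rep(0, 3)))
  expect_equal(map_feature_nodes(X, id_map, cfg), X)
  b_map <- list(list(weights = diag(3), bias = c(1, -2, 3)))
  Z0 <- map_feature_nodes(matrix(0, 4, 3), b_map, cfg)
  expect_equal(Z0, matrix(c(1, -2, 3), 4, 3, byrow = TRUE))
  # per-element loop oracle over two groups
  cfg2 <- bls_config(n_feature_groups = 2L, nodes_per_group = 2L,
                     feature_activation = "tanh", seed = 3L)
  maps <- init_random_maps(cfg2, 3L)
  Z <- map_feature_nodes(X, maps, cfg2)
  oracle <- matrix(NA_real_, 5, 4)
  for (g in 1:2) for (r in 1:5) for (c in 1:2) {
    acc <- maps[[g]]$bias[c]
    for (j in 1:3) acc <- acc + X[r, j] * maps[[g]]$weights[j, c]
    oracle[r, (g - 1) * 2 + c] <- tanh(acc)
  }
  expect_equal(Z, oracle)
  expect_error(map_feature_nodes(X[, 1:2], maps, cfg2),
               class = "cigbls_invalid_argument")
})

test_that("enhancement mapping: zero map, tanh range, loop oracle", {
  cfg <- bls_config(enh_activation = "tanh", seed = 2L)
  Z <- matrix(rnorm(8), 4, 2)
  zero_map <- list(list(weights = matrix(0, 2, 3), bias = rep(0, 3)))
  expect_equal(map_enhancement_nodes(Z, zero_map, cfg), matrix(0, 4, 3))
  cfg3 <- bls_config(n_enh_groups = 2L, nodes_per_enh_group = 3L,
                     enh_activation = "tanh", seed = 5L)
  emaps <- cigbls:::init_enh_maps(cfg3, 2L)
  H <- map_enhancement_nodes(Z, emaps, cfg3)
  expect_true(all(H > -1 & H < 1))
  oracle <- do.call(cbind, lapply(emaps, function(m)
    tanh(Z %*% m$weights + matrix(m$bias, 4, 3, byrow = TRUE))))
  expect_equal(H, oracle)
})

test_that("solve_ridge: identity design, shrinkage, dense-inverse oracle", {
  Y <- matrix(rnorm(8), 4, 2)
  expect_equal(solve_ridge(diag(4), Y, 0), Y)
  sys <- rand_system(6, 4, 2, seed = 10)
  # dense-inverse oracle
  for (lam in c(0, 0.1, 3)) {
    W_oracle <- solve(lam * diag(4) + t(sys$A) %*% sys$A) %*% t(sys$A) %*% sys$Y
    expect_equal(solve_ridge(sys$A, sys$Y, lam), W_oracle, tolerance = 1e-10)
  }
  # shrinkage monotone in lambda, with ||W|| -> 0
  norms <- vapply(c(0, 1e-2, 1, 1e3, 1e6, 1e9),
                  function(l) cigbls:::frob(solve_ridge(sys$A, sys$Y, l)), 0)
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[length(norms)], 1e-5)
  expect_error(solve_ridge(sys$A, sys$Y, -1), class = "cigbls_invalid_argument")
})

test_that("rank-deficient system at lambda=0 falls back with a warning", {
  A <- cbind(1:5, 1:5, rnorm(5))        # duplicated column
  Y <- matrix(rnorm(5))
  expect_warning(W <- solve_ridge(A, Y, 0), "rank-deficient")
  expect_true(all(is.finite(W)))
  # pseudo-inverse fallback still reproduces the least-squares fitted values
  expect_equal(A %*% W, qr.fitted(qr(A), Y), tolerance = 1e-8)
})

test_that("ridge solution minimizes the objective; interpolation limit", {
  obj <- function(W, A, Y, lam) sum((Y - A %*% W)^2) + lam * sum(W^2)
  for (s in 1:5) {
    sys <- rand_system(8, 5, 1, seed = s)
    lam <- 0.3
    W <- solve_ridge(sys$A, sys$Y, lam)
    j0 <- obj(W, sys$A, sys$Y, lam)
    for (i in seq_along(W)) for (eps in c(1e-4, -1e-4)) {
      Wp <- W; Wp[i] <- Wp[i] + eps
      expect_gte(obj(Wp, sys$A, sys$Y, lam), j0)
    }
  }
  # N <= L, full row rank, lambda -> 0: training residual ~ 0
  sys <- rand_system(6, 9, 1, seed = 77)
  W <- solve_ridge(sys$A, sys$Y, 1e-12)
  expect_lt(cigbls:::frob(sys$A %*% W - sys$Y), 1e-4)
})

test_that("predict_state and fit_bls are deterministic and conformable", {
  sys <- rand_system(5, 3, 2, seed = 2)
  expect_equal(predict_state(sys$A, matrix(0, 3, 2)), matrix(0, 5, 2))
  onehot <- diag(3)[c(2, 1, 3, 2, 1), ]
  W <- matrix(rnorm(6), 3, 2)
  expect_equal(predict_state(onehot, W), W[c(2, 1, 3, 2, 1), ])
  expect_error(predict_state(sys$A, matrix(0, 4, 2)),
               class = "cigbls_invalid_argument")
  set.seed(3)
  X <- matrix(runif(60), 20, 3); Y <- matrix(rowSums(X^2))
  cfg <- bls_config(n_feature_groups = 2L, nodes_per_group = 4L,
                    n_enh_groups = 1L, nodes_per_enh_group = 6L, seed = 9L)
  f1 <- fit_bls(X, Y, cfg); f2 <- fit_bls(X, Y, cfg)
  expect_identical(f1$W, f2$W)
  Xn <- matrix(runif(15), 5, 3)
  expect_identical(predict(f1, Xn), predict(f2, Xn))
})
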