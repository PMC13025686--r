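test_that("anchor regularizer: normalization, row-stochastic S_hat, oracle", {
  set.seed(1)
  # hand/dense oracle on a 5x3 example
  H <- matrix(runif(15, 0.05, 1), 5, 3)
  reg <- build_anchor_regularizer(H, beta = 0.05)
  expect_equal(rowSums(reg$H_bar), rep(1, 5), tolerance = 1e-12)
  expect_equal(reg$delta_diag, colSums(reg$H_bar))
  S_hat <- reg$H_bar %*% diag(1 / reg$delta_diag) %*% t(reg$H_bar)
  expect_equal(S_hat, reg$H_bar %*% (t(reg$H_bar) / reg$delta_diag))
  # S_hat rows sum to 1 over random instances
  for (s in 1:10) {
    set.seed(s)
    Hr <- matrix(runif(8 * 4, 1e-3, 1), 8, 4)
    rr <- build_anchor_regularizer(Hr, 0.1)
    Sr <- rr$H_bar %*% (t(rr$H_bar) / rr$delta_diag)
    expect_equal(rowSums(Sr), rep(1, 8), tolerance = 1e-10)
  }
  # hard-assignment limit: one nonzero per row -> S_hat block-constant 1/n_k
  Hh <- matrix(0, 6, 2); Hh[cbind(1:6, c(1, 1, 1, 2, 2, 2))] <- runif(6, 0.2, 1)
  rh <- build_anchor_regularizer(Hh, 0)
  Sh <- rh$H_bar %*% (t(rh$H_bar) / rh$delta_diag)
  expect_equal(Sh, kronecker(diag(2), matrix(1 / 3, 3, 3)))
  expect_error(build_anchor_regularizer(rbind(Hh, 0), 0),
               class = "cigbls_invalid_argument")
  expect_error(build_anchor_regularizer(-Hh, 0),
               class = "cigbls_invalid_argument")
})

test_that("reduced-rank quadratic form equals the dense construction", {
  for (s in 1:5) {
    st <- small_ci_state(seed = s, n = 20L + 5L * s)
    reg <- build_anchor_regularizer(st$H, 0.05)
    R <- reduced_rank_regularizer(st$A, reg)
    A <- st$A$values
    dense <- t(A) %*% dense_anchor_laplacian(reg) %*% A
    expect_equal(R, dense, tolerance = 1e-9)
    expect_equal(R, t(R), tolerance = 1e-9)
  }
})

test_that("solve_manifold: ridge limit, optimizer oracle, 1/(1+beta) law", {
  st <- small_ci_state(seed = 3)
  reg <- build_anchor_regularizer(st$H, 0)
  W_ridge <- solve_ridge(st$A$values, st$Y, 0.01)
  expect_equal(solve_manifold(st$A, st$Y, 0.01, reg, beta = 0), W_ridge,
               tolerance = 1e-12)
  # generic numerical optimizer finds the same minimizer of the objective
  sys <- rand_system(12, 5, 1, seed = 8)
  Hs <- matrix(runif(12 * 3, 0.1, 1), 12, 3)
  rs <- build_anchor_regularizer(Hs, 0.2)
  W_cf <- solve_manifold(sys$A, sys$Y, 0.05, rs)
  opt <- optim(rep(0, 5),
               fn = function(w) manifold_objective(matrix(w), sys$A, sys$Y,
                                                   0.05, rs)$value,
               gr = function(w) as.vector(manifold_objective(matrix(w), sys$A,
                                                             sys$Y, 0.05, rs)$gradient),
               method = "BFGS", control = list(maxit = 1000, reltol = 1e-15))
  expect_equal(as.vector(W_cf), opt$par, tolerance = 1e-6)
  # identity-Laplacian, lambda = 0 limit: W scales exactly as 1/(1+beta)
  W0 <- solve_manifold(sys$A, sys$Y, 0, reg = NULL, beta = 0)
  W1 <- solve_manifold(sys$A, sys$Y, 0, reg = NULL, beta = 1)
  expect_equal(W1, W0 / 2, tolerance = 1e-12)
})

test_that("dense kNN Laplacian oracle: graph structure and trace identity", {
  set.seed(6)
  X <- matrix(rnorm(8 * 3), 8, 3)
  g_full <- build_dense_lap_oracle(X, 7L)           # k = N-1: complete graph
  expect_true(all(g_full$adjacency[upper.tri(g_full$adjacency)] == 1L))
  g <- build_dense_lap_oracle(X, 3L)
  expect_identical(g$adjacency, t(g$adjacency))     # "or"-rule symmetry
  expect_equal(rowSums(g$laplacian), rep(0, 8), tolerance = 1e-12)
  ev <- eigen(g$laplacian, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))                      # PSD
  # J_MR trace form equals the half double-sum form
  Yhat <- matrix(rnorm(16), 8, 2)
  tr_form <- sum(diag(t(Yhat) %*% g$laplacian %*% Yhat))
  dbl <- 0
  for (p in 1:8) for (q in 1:8)
    dbl <- dbl + g$weights[p, q] * sum((Yhat[p, ] - Yhat[q, ])^2)
  expect_equal(tr_form, dbl / 2, tolerance = 1e-10)
  expect_error(build_dense_lap_oracle(X, 8L), class = "cigbls_invalid_argument")
})

test_that("solve_dense_lap matches ridge, an optimizer, and the reduced-rank path", {
  sys <- rand_system(10, 4, 1, seed = 12)
  g <- build_dense_lap_oracle(sys$A, 3L)
  expect_equal(solve_dense_lap(sys$A, sys$Y, 0.1, 0, g),
               solve_ridge(sys$A, sys$Y, 0.1), tolerance = 1e-12)
  # numerical minimization of the dense objective
  beta <- 0.3; lam <- 0.05
  obj <- function(w) {
    W <- matrix(w); R <- sys$A %*% W - sys$Y
    sum(R^2) + lam * sum(W^2) +
      beta * sum(diag(t(W) %*% t(sys$A) %*% g$laplacian %*% sys$A %*% W))
  }
  W_cf <- solve_dense_lap(sys$A, sys$Y, lam, beta, g)
  opt <- optim(rep(0, 4), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))
  expect_equal(as.vector(W_cf), opt$par, tolerance = 1e-5)
  # key reduced-rank equivalence: L = I - S_hat densely vs solve_manifold
  st <- small_ci_state(seed = 21, n = 40L)
  reg <- build_anchor_regularizer(st$H, 0.07)
  W_fast <- solve_manifold(st$A, st$Y, 0.01, reg)
  W_dense <- solve_dense_lap(st$A, st$Y, 0.01, 0.07,
                             dense_anchor_laplacian(reg))
  expect_equal(W_fast, W_dense, tolerance = 1e-10)
})

test_that("stationarity and monotone smoothing of the manifold solution", {
  for (s in 1:5) {
    st <- small_ci_state(seed = 30 + s)
    reg <- build_anchor_regularizer(st$H, 0.1)
    W <- solve_manifold(st$A, st$Y, 0.02, reg)
    gr <- manifold_objective(W, st$A, st$Y, 0.02, reg)$gradient
    expect_lt(cigbls:::frob(gr), 1e-8 * max(1, cigbls:::frob(W)))
  }
  st <- small_ci_state(seed = 55, n = 40L)
  reg0 <- build_anchor_regularizer(st$H, 0)
  AtLA <- reduced_rank_regularizer(st$A, reg0)
  smooth <- vapply(c(0, 0.01, 0.1, 0.5, 1, 5), function(b) {
    W <- solve_manifold(st$A, st$Y, 0.01, reg0, beta = b)
    sum(diag(t(W) %*% AtLA %*% W))
  }, 0)
  expect_true(all(diff(smooth) <= 1e-10))
})

test_that("no N x N allocation in the reduced-rank path at N = 10^4", {
  set.seed(2)
  n <- 10000L
  H <- matrix(runif(n * 20, 1e-3, 1), n, 20)
  A <- matrix(rnorm(n * 30), n, 30)
  reg <- build_anchor_regularizer(H, 0.05)
  if (isTRUE(unname(capabilities("profmem")))) {
    pm <- tempfile()
    Rprofmem(pm)
    R <- reduced_rank_regularizer(A, reg)
    Rprofmem(NULL)
    allocs <- suppressWarnings(
      as.numeric(sub(":.*", "", grep("^[0-9]+ :", readLines(pm), value = TRUE))))
    # largest single allocation must stay far below an N x N double block
    expect_lt(max(allocs, 0), 0.5 * n * n * 8)
    unlink(pm)
  } else {
    R <- reduced_rank_regularizer(A, reg)
  }
  expect_identical(dim(R), c(30L, 30L))
  expect_true(all(is.finite(R)))
  expect_equal(R, t(R), tolerance = 1e-8)
})
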