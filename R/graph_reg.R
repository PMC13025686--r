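# Anchor-graph reduced-rank manifold regularizer, the analytic solver, and a
# dense kNN-Laplacian oracle used only for verification at small N.
#
# The manifold penalty Tr(W'A'LAW) uses the random-walk normalized Laplacian
# L = I - S_hat with the low-rank, row-stochastic similarity
# S_hat = Hbar Delta^{-1} Hbar', where Hbar is the row-normalized enhancement
# matrix and Delta_kk = sum_j Hbar_jk. The quadratic form A'LA is always
# computed through N x m products; the N x N similarity is never formed
# outside the oracle path.

#' Build the anchor-graph regularizer
#'
#' Row-normalizes the (nonnegative) enhancement matrix `H` to `Hbar` and
#' accumulates the anchor degrees `Delta_kk = sum_j Hbar_jk`. Degrees of dead
#' anchors (no similarity mass) are floored at 1e-12 with a warning so the
#' reduced-rank form stays well defined.
#'
#' @param H nonnegative matrix of sample-to-anchor affinities (samples x m);
#'   with RBF enhancement nodes every entry is in (0, 1].
#' @param beta manifold regularization strength (>= 0).
#' @return An object of class `graph_regularizer` with `H_bar`,
#'   `delta_diag`, and `beta`.
#' @export
build_anchor_regularizer <- function(H, beta = 0.05) {
  H <- check_matrix(H)
  if (any(H < 0)) stop_invalid("H must be nonnegative")
  if (beta < 0) stop_invalid("beta must be >= 0")
  rs <- rowSums(H)
  if (any(rs <= 0))
    stop_invalid("H has an all-zero row; cannot row-normalize")
  H_bar <- H / rs
  delta <- colSums(H_bar)
  if (any(delta <= 0)) {
    warning("dead anchors: flooring zero degrees at 1e-12", call. = FALSE)
    delta <- pmax(delta, 1e-12)
  }
  structure(list(H_bar = H_bar, delta_diag = delta, beta = beta),
            class = "graph_regularizer")
}

#' Reduced-rank quadratic form A'LA
#'
#' Computes `A'LA = A'A - (A'Hbar) Delta^{-1} (Hbar'A)` without ever forming
#' an N x N matrix; only N x m and L x m products are used. Independent of
#' `beta`.
#'
#' @param A state matrix (or `state_matrix` object).
#' @param reg a [build_anchor_regularizer()] result.
#' @return The L x L matrix `A'LA`.
#' @export
reduced_rank_regularizer <- function(A, reg) {
  A <- state_values(A)
  if (nrow(A) != nrow(reg$H_bar))
    stop_invalid("A and H_bar must have equal row counts")
  AtH <- crossprod(A, reg$H_bar)                       # L x m
  crossprod(A) - AtH %*% (t(AtH) / reg$delta_diag)     # L x L
}

#' Analytic manifold-regularized solve for the output weights
#'
#' Solves the normal equations of the anchor-graph objective,
#' `((1+beta) A'A - beta (A'Hbar) Delta^{-1} (Hbar'A) + lambda I) W = A'Y`,
#' by one stable Cholesky solve; no iteration. With `beta = 0` this reduces
#' exactly to [solve_ridge()]. Passing `reg = NULL` drops the similarity
#' term entirely (Laplacian = identity), the limit in which the solution is
#' the ridge solution shrunk by `1/(1+beta)` when `lambda = 0`.
#'
#' @param A state matrix. @param Y targets.
#' @param lambda_reg ridge penalty (>= 0).
#' @param reg a `graph_regularizer`, or `NULL` for the identity-Laplacian
#'   limit.
#' @param beta overrides `reg$beta` when given.
#' @return The output-weight matrix `W`.
#' @export
solve_manifold <- function(A, Y, lambda_reg, reg = NULL, beta = NULL) {
  A <- state_values(A); Y <- check_matrix(Y)
  if (nrow(A) != nrow(Y)) stop_invalid("A and Y must have equal row counts")
  if (lambda_reg < 0) stop_invalid("lambda_reg must be >= 0")
  beta <- beta %||% (if (is.null(reg)) 0 else reg$beta)
  M <- (1 + beta) * crossprod(A)
  if (!is.null(reg) && beta > 0) {
    AtH <- crossprod(A, reg$H_bar)
    M <- M - beta * AtH %*% (t(AtH) / reg$delta_diag)
  }
  diag(M) <- diag(M) + lambda_reg
  solve_spd(M, crossprod(A, Y), context = "manifold-regularized system")
}

#' Dense kNN graph Laplacian (small-N oracle)
#'
#' Builds the symmetric k-nearest-neighbour graph under the "or" rule
#' (an edge exists if either point is among the other's k nearest), weights
#' retained edges with a Gaussian kernel `exp(-d^2 / (2 sigma^2))`, and
#' returns the unnormalized Laplacian `L = D - S`. Ties in neighbour
#' distance are broken by lower index. Quadratic in N by construction —
#' verification use only.
#'
#' @param X points (rows); typically the enhancement representation.
#' @param k_neighbors neighbours per point, `< nrow(X)`.
#' @param sigma Gaussian kernel width; defaults to the median distance over
#'   retained edges.
#' @return An object of class `dense_graph` with `adjacency`, `weights`,
#'   `degree`, `laplacian`, and `sigma`.
#' @export
build_dense_lap_oracle <- function(X, k_neighbors, sigma = NULL) {
  X <- check_matrix(X)
  n <- nrow(X)
  k_neighbors <- check_count(k_neighbors)
  if (k_neighbors >= n) stop_invalid("k_neighbors must be < nrow(X)")
  d2 <- sqdist_cross(X, X)
  G <- matrix(0L, n, n)
  for (p in seq_len(n)) {
    ord <- order(d2[p, ], seq_len(n))   # ties broken by lower index
    nb <- setdiff(ord, p)[seq_len(k_neighbors)]
    G[p, nb] <- 1L
  }
  G <- (G | t(G)) * 1L                  # "or" symmetrization
  diag(G) <- 0L
  edge_d2 <- d2[G == 1L]
  sigma <- sigma %||% stats::median(sqrt(edge_d2))
  if (sigma <= 0) sigma <- 1           # duplicate-point degenerate case
  S <- G * exp(-d2 / (2 * sigma^2))
  D <- rowSums(S)
  structure(list(adjacency = G, weights = S, degree = D,
                 laplacian = diag(D, n) - S, sigma = sigma,
                 k_neighbors = k_neighbors), class = "dense_graph")
}

#' Dense manifold-regularized solve (oracle)
#'
#' Solves `(A'A + lambda I + beta A'LA) W = A'Y` with an explicitly formed
#' Laplacian; `graph` may be a `dense_graph`, or any N x N Laplacian matrix
#' (e.g. `I - S_hat` built densely from an anchor graph for equivalence
#' checks).
#'
#' @param A state matrix. @param Y targets. @param lambda_reg ridge penalty.
#' @param beta manifold strength.
#' @param graph `dense_graph` object or Laplacian matrix.
#' @return The output-weight matrix `W`.
#' @export
solve_dense_lap <- function(A, Y, lambda_reg, beta, graph) {
  A <- state_values(A); Y <- check_matrix(Y)
  L <- if (inherits(graph, "dense_graph")) graph$laplacian else check_matrix(graph)
  if (nrow(L) != nrow(A)) stop_invalid("Laplacian and A sizes disagree")
  M <- crossprod(A) + beta * crossprod(A, L %*% A)
  diag(M) <- diag(M) + lambda_reg
  solve_spd(M, crossprod(A, Y), context = "dense manifold system")
}

#' Dense anchor-graph Laplacian (oracle)
#'
#' Explicitly forms `I - Hbar Delta^{-1} Hbar'` for small-N equivalence
#' tests of the reduced-rank path.
#'
#' @param reg a `graph_regularizer`.
#' @return The N x N matrix `I - S_hat`.
#' @export
dense_anchor_laplacian <- function(reg) {
  S_hat <- reg$H_bar %*% (t(reg$H_bar) / reg$delta_diag)
  diag(nrow(S_hat)) - S_hat
}

#' Manifold objective value and gradient
#'
#' The anchor-graph objective
#' `J(W) = ||AW - Y||_F^2 + lambda ||W||_F^2 + beta Tr(W'A'LAW)` and its
#' gradient, used by stationarity tests and by numerical-minimizer oracles.
#'
#' @inheritParams solve_manifold
#' @param W candidate weights.
#' @return A list with `value` and `gradient`.
#' @export
manifold_objective <- function(W, A, Y, lambda_reg, reg = NULL, beta = NULL) {
  A <- state_values(A)
  W <- check_matrix(W)
  beta <- beta %||% (if (is.null(reg)) 0 else reg$beta)
  R <- A %*% W - Y
  AtLAW <- if (is.null(reg)) crossprod(A, A %*% W)
           else reduced_rank_regularizer(A, reg) %*% W
  value <- sum(R * R) + lambda_reg * sum(W * W) + beta * sum(W * AtLAW)
  gradient <- 2 * crossprod(A, R) + 2 * lambda_reg * W + 2 * beta * AtLAW
  list(value = value, gradient = gradient)
}
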