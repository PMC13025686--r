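# Standard broad learning system: random feature/enhancement mappings and
# the shared closed-form ridge solver.

activation_fun <- function(name) {
  switch(name,
         linear  = identity,
         tanh    = tanh,
         sigmoid = function(x) 1 / (1 + exp(-x)),
         stop_invalid("unknown activation '", name, "'"))
}

#' Configuration for a standard (fully connected) broad learning system
#'
#' A flat network maps the input through `n_feature_groups` random linear
#' groups of `nodes_per_group` feature nodes each, expands them through
#' `n_enh_groups` nonlinear groups of `nodes_per_enh_group` enhancement
#' nodes, and connects every node linearly to the output. Output weights are
#' obtained by one ridge solve; no backpropagation is involved.
#'
#' @param n_feature_groups number of feature-node groups.
#' @param nodes_per_group feature nodes per group.
#' @param n_enh_groups number of enhancement-node groups.
#' @param nodes_per_enh_group enhancement nodes per group.
#' @param lambda_reg ridge penalty on the output weights (>= 0).
#' @param xi_scale scaling of the enhancement block in the state matrix
#'   (> 0; 0.5 balances the two blocks).
#' @param feature_activation activation for feature nodes: "linear" or "tanh".
#' @param enh_activation activation for enhancement nodes: "tanh" or "sigmoid".
#' @param weight_init_range interval the random weights/biases are drawn
#'   uniformly from.
#' @param seed master seed for all random maps.
#' @return An object of class `bls_config`.
#' @export
bls_config <- function(n_feature_groups = 18L, nodes_per_group = 10L,
                       n_enh_groups = 1L, nodes_per_enh_group = 180L,
                       lambda_reg = 1e-2, xi_scale = 0.5,
                       feature_activation = c("linear", "tanh"),
                       enh_activation = c("tanh", "sigmoid"),
                       weight_init_range = c(-1, 1), seed = 1L) {
  cfg <- list(
    n_feature_groups = check_count(n_feature_groups),
    nodes_per_group = check_count(nodes_per_group),
    n_enh_groups = check_count(n_enh_groups),
    nodes_per_enh_group = check_count(nodes_per_enh_group),
    lambda_reg = lambda_reg,
    xi_scale = xi_scale,
    feature_activation = match.arg(feature_activation),
    enh_activation = match.arg(enh_activation),
    weight_init_range = as.numeric(weight_init_range),
    seed = as.integer(seed))
  if (cfg$lambda_reg < 0) stop_invalid("lambda_reg must be >= 0")
  if (cfg$xi_scale <= 0) stop_invalid("xi_scale must be > 0")
  if (length(cfg$weight_init_range) != 2L ||
      diff(cfg$weight_init_range) <= 0)
    stop_invalid("weight_init_range must be a nonempty interval")
  structure(cfg, class = "bls_config")
}

#' Initialize the random feature maps of a BLS
#'
#' Draws `n_feature_groups` weight matrices (`input_dim x nodes_per_group`)
#' and bias vectors i.i.d. uniform on `weight_init_range`. Maps are generated
#' once and remain fixed; each group draws from its own sub-stream of the
#' master seed (see [sub_seed()]).
#'
#' @param config a [bls_config()].
#' @param input_dim number of input variables.
#' @return A list of `RandomMap`s, each with `weights` and `bias`.
#' @export
init_random_maps <- function(config, input_dim) {
  input_dim <- check_count(input_dim)
  lo <- config$weight_init_range[1]; hi <- config$weight_init_range[2]
  lapply(seq_len(config$n_feature_groups), function(i) {
    with_seed(sub_seed(config$seed, i), list(
      weights = matrix(runif(input_dim * config$nodes_per_group, lo, hi),
                       input_dim, config$nodes_per_group),
      bias = runif(config$nodes_per_group, lo, hi)))
  })
}

init_enh_maps <- function(config, feature_dim) {
  lo <- config$weight_init_range[1]; hi <- config$weight_init_range[2]
  lapply(seq_len(config$n_enh_groups), function(j) {
    with_seed(sub_seed(config$seed, 10000L + j), list(
      weights = matrix(runif(feature_dim * config$nodes_per_enh_group, lo, hi),
                       feature_dim, config$nodes_per_enh_group),
      bias = runif(config$nodes_per_enh_group, lo, hi)))
  })
}

apply_random_map <- function(X, map, act) {
  if (ncol(X) != nrow(map$weights))
    stop_invalid("input has ", ncol(X), " columns but map expects ",
                 nrow(map$weights))
  act(sweep(X %*% map$weights, 2L, map$bias, "+"))
}

#' Map inputs to feature nodes
#'
#' Applies each random group map `Z_i = phi(X W_i + b_i)` and concatenates
#' the groups column-wise in order.
#'
#' @param X input matrix (one sample per row).
#' @param maps list from [init_random_maps()].
#' @param config the [bls_config()] that created the maps.
#' @return The feature-node matrix `Z` with `n_feature_groups *
#'   nodes_per_group` columns.
#' @export
map_feature_nodes <- function(X, maps, config) {
  X <- check_matrix(X)
  act <- activation_fun(config$feature_activation)
  do.call(cbind, lapply(maps, function(m) apply_random_map(X, m, act)))
}

#' Map feature nodes to enhancement nodes
#'
#' Applies `H_j = psi(Z W_j + b_j)` per enhancement group and concatenates.
#'
#' @param Z feature-node matrix.
#' @param maps list of enhancement random maps.
#' @param config the governing [bls_config()].
#' @return The enhancement matrix `H`.
#' @export
map_enhancement_nodes <- function(Z, maps, config) {
  Z <- check_matrix(Z)
  act <- activation_fun(config$enh_activation)
  do.call(cbind, lapply(maps, function(m) apply_random_map(Z, m, act)))
}

#' Closed-form ridge solve for the output weights
#'
#' Solves `min_W ||Y - A W||_F^2 + lambda ||W||_F^2`, i.e.
#' `W = (lambda I + A'A)^{-1} A'Y`, by a Cholesky factorization of the
#' normal equations (never an explicit inverse). A numerically
#' rank-deficient system (possible at `lambda = 0`) falls back to the
#' pseudo-inverse with a warning.
#'
#' @param A state matrix (samples x nodes).
#' @param Y target matrix (samples x outputs).
#' @param lambda_reg ridge penalty, >= 0.
#' @return The output-weight matrix `W` (nodes x outputs).
#' @export
solve_ridge <- function(A, Y, lambda_reg) {
  A <- check_matrix(A); Y <- check_matrix(Y)
  if (nrow(A) != nrow(Y)) stop_invalid("A and Y must have equal row counts")
  if (lambda_reg < 0) stop_invalid("lambda_reg must be >= 0")
  M <- crossprod(A)
  diag(M) <- diag(M) + lambda_reg
  solve_spd(M, crossprod(A, Y), context = "lambda*I + A'A")
}

#' Predict from a state matrix and output weights
#'
#' @param A state matrix.
#' @param W output weights.
#' @return `A %*% W`.
#' @export
predict_state <- function(A, W) {
  A <- check_matrix(A); W <- check_matrix(W)
  if (ncol(A) != nrow(W)) stop_invalid("A and W are not conformable")
  A %*% W
}

#' Fit a standard fully connected BLS
#'
#' Baseline estimator: random feature nodes, random nonlinear enhancement
#' nodes, state matrix `A = [Z | xi H]`, one ridge solve.
#'
#' @param X input matrix. @param Y target matrix (or vector).
#' @param config a [bls_config()].
#' @return An object of class `bls_fit` with the frozen maps and weights.
#' @export
fit_bls <- function(X, Y, config = bls_config()) {
  X <- check_matrix(X); Y <- check_matrix(Y)
  fmaps <- init_random_maps(config, ncol(X))
  Z <- map_feature_nodes(X, fmaps, config)
  emaps <- init_enh_maps(config, ncol(Z))
  H <- map_enhancement_nodes(Z, emaps, config)
  A <- cbind(Z, config$xi_scale * H)
  W <- solve_ridge(A, Y, config$lambda_reg)
  structure(list(config = config, feature_maps = fmaps, enh_maps = emaps,
                 W = W), class = "bls_fit")
}

#' @export
predict.bls_fit <- function(object, newdata, ...) {
  Z <- map_feature_nodes(check_matrix(newdata), object$feature_maps,
                         object$config)
  H <- map_enhancement_nodes(Z, object$enh_maps, object$config)
  predict_state(cbind(Z, object$config$xi_scale * H), object$W)
}
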