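# The CI-GBLS estimator: channel-independent feature mapping, per-channel
# K-Means anchors, RBF enhancement, anchor-graph manifold-regularized
# closed-form solve; plus grid search, ablation and sensitivity drivers.

#' Configuration for the CI-GBLS estimator
#'
#' Defaults follow the reference configuration for an 18-variable process:
#' 10 feature nodes and 10 anchors per channel (180 of each in total),
#' `xi = 0.5`, `lambda = 1e-3`, `gamma = 0.1`, `beta = 0.05`.
#'
#' @param nodes_per_channel feature nodes per input channel.
#' @param anchors_per_channel K-Means anchors (= RBF enhancement nodes) per
#'   channel.
#' @param gamma RBF kernel width (> 0; larger = narrower kernels).
#' @param lambda_reg ridge penalty on the output weights.
#' @param beta manifold regularization strength; 0 disables the anchor
#'   graph.
#' @param xi_scale scaling of the enhancement block in `A = [Z | xi H]`.
#' @param feature_activation activation of the channel feature maps.
#' @param weight_init_range uniform draw interval for the random maps.
#' @param kmeans_iters Lloyd iteration cap for anchor fitting.
#' @param channel_independent `FALSE` replaces the isolated channels with a
#'   fully connected random feature map and global K-Means anchors (the
#'   "w/o CI" ablation), keeping the total node budget identical.
#' @param seed master seed; every random draw in the fit derives from it.
#' @return An object of class `cigbls_config`.
#' @export
cigbls_config <- function(nodes_per_channel = 10L, anchors_per_channel = 10L,
                          gamma = 0.1, lambda_reg = 1e-3, beta = 0.05,
                          xi_scale = 0.5,
                          feature_activation = c("linear", "tanh"),
                          weight_init_range = c(-1, 1), kmeans_iters = 100L,
                          channel_independent = TRUE, seed = 1L) {
  if (gamma < 0) stop_invalid("gamma must be >= 0")
  if (lambda_reg < 0) stop_invalid("lambda_reg must be >= 0")
  if (beta < 0) stop_invalid("beta must be >= 0")
  if (xi_scale <= 0) stop_invalid("xi_scale must be > 0")
  structure(list(
    nodes_per_channel = check_count(nodes_per_channel),
    anchors_per_channel = check_count(anchors_per_channel),
    gamma = gamma, lambda_reg = lambda_reg, beta = beta,
    xi_scale = xi_scale,
    feature_activation = match.arg(feature_activation),
    weight_init_range = as.numeric(weight_init_range),
    kmeans_iters = check_count(kmeans_iters),
    channel_independent = isTRUE(channel_independent),
    seed = as.integer(seed)), class = "cigbls_config")
}

# Feature mapping stage shared by fit and predict. For the fully connected
# ablation one global random map consumes all M variables (same total width
# M * nodes_per_channel) and everything lives in a single "channel".
cigbls_feature_stage <- function(X, config, maps = NULL) {
  M <- ncol(X)
  if (config$channel_independent) {
    maps <- maps %||% init_channel_maps(M, config$nodes_per_channel,
                                        config$weight_init_range,
                                        sub_seed(config$seed, 1L))
    fm <- ci_feature_map(X, maps, config$feature_activation)
    list(maps = maps, Z = fm$Z, layout = fm$layout)
  } else {
    if (is.null(maps)) {
      lo <- config$weight_init_range[1]; hi <- config$weight_init_range[2]
      width <- M * config$nodes_per_channel
      maps <- with_seed(sub_seed(config$seed, 1L), list(
        weights = matrix(runif(M * width, lo, hi), M, width),
        bias = runif(width, lo, hi)))
    }
    act <- activation_fun(config$feature_activation)
    list(maps = maps, Z = apply_random_map(X, maps, act),
         layout = rep(1L, ncol(maps$weights)))
  }
}

#' Fit a CI-GBLS soft sensor
#'
#' Composes the full closed-form training path: channel-independent feature
#' mapping, per-channel K-Means anchors, RBF enhancement, state-matrix
#' assembly `A = [Z | xi H]`, anchor-graph regularizer from the raw
#' enhancement matrix, and one manifold-regularized linear solve for the
#' output weights. Anchors, random maps and the regularizer depend on the
#' training data only and are frozen for prediction.
#'
#' @param X training inputs (samples x variables), already windowed/scaled.
#' @param Y training targets (vector or samples x C matrix).
#' @param config a [cigbls_config()].
#' @return An object of class `cigbls_fit` with frozen maps, anchors,
#'   weights, training metrics and `train_time_s`.
#' @export
fit_cigbls <- function(X, Y, config = cigbls_config()) {
  X <- check_matrix(X); Y <- check_matrix(Y)
  t0 <- proc.time()[["elapsed"]]
  fs <- cigbls_feature_stage(X, config)
  # the "w/o CI" variant keeps the total anchor budget by clustering the
  # full feature space with M * anchors_per_channel centers
  m_k <- if (config$channel_independent) config$anchors_per_channel
         else config$anchors_per_channel * ncol(X)
  anchors <- fit_channel_anchors(fs$Z, fs$layout, m_k, config$gamma,
                                 seed = sub_seed(config$seed, 2L),
                                 iters = config$kmeans_iters)
  enh <- rbf_enhance(fs$Z, fs$layout, anchors)
  A <- assemble_state(fs$Z, enh$H, config$xi_scale, fs$layout, enh$layout)
  reg <- if (config$beta > 0) build_anchor_regularizer(enh$H, config$beta)
         else NULL
  W <- solve_manifold(A, Y, config$lambda_reg, reg, beta = config$beta)
  Yhat <- predict_state(A$values, W)
  fit <- structure(list(
    config = config, feature_maps = fs$maps, layout = fs$layout,
    anchors = anchors, W = W,
    n_feature_nodes = A$n_feature_nodes, n_enh_nodes = A$n_enh_nodes,
    metrics = compute_metrics(Y[, 1L], Yhat[, 1L]),
    train_time_s = proc.time()[["elapsed"]] - t0), class = "cigbls_fit")
  fit
}

#' Predict from a fitted CI-GBLS model
#'
#' Reapplies the frozen random maps and anchors to new inputs and multiplies
#' by the learned output weights.
#'
#' @param object a `cigbls_fit`. @param newdata input matrix on the same
#'   variables/scaling as training. @param ... unused.
#' @return Prediction matrix (samples x C).
#' @export
predict.cigbls_fit <- function(object, newdata, ...) {
  X <- check_matrix(newdata)
  fs <- cigbls_feature_stage(X, object$config, maps = object$feature_maps)
  enh <- rbf_enhance(fs$Z, fs$layout, object$anchors)
  A <- cbind(fs$Z, object$config$xi_scale * enh$H)
  predict_state(A, object$W)
}

#' @export
print.cigbls_fit <- function(x, ...) {
  cat(sprintf("CI-GBLS fit: %d feature + %d enhancement nodes (%s)\n",
              x$n_feature_nodes, x$n_enh_nodes,
              if (x$config$channel_independent) "channel-independent"
              else "fully connected"))
  cat(sprintf("  lambda=%g gamma=%g beta=%g xi=%g seed=%d\n",
              x$config$lambda_reg, x$config$gamma, x$config$beta,
              x$config$xi_scale, x$config$seed))
  cat(sprintf("  train RMSE %.4g  MAE %.4g  R2 %.4f  (%.2f s)\n",
              x$metrics$rmse, x$metrics$mae, x$metrics$r2, x$train_time_s))
  invisible(x)
}

#' Exhaustive grid search over lambda, gamma, beta
#'
#' Holds out `val_frac` of the training batches (batch granularity) as a
#' validation set, fits every combination on the remaining batches and
#' selects the configuration with minimum validation RMSE. Ties are broken
#' by smaller `beta`, then larger `lambda`.
#'
#' @param X,Y,groups training design, targets, and batch id per row.
#' @param config base [cigbls_config()] supplying all non-searched fields.
#' @param lambda_grid,gamma_grid,beta_grid candidate values; defaults span
#'   `lambda` in `[1e-4, 10]` and `gamma` in `[1e-4, 1]` log-uniformly and
#'   `beta` in `{0, 0.01, 0.05}`.
#' @param val_frac fraction of batches held out for validation.
#' @param seed seed for the validation split.
#' @return A list with `best` (a `cigbls_config`), `best_rmse`, and the
#'   full `results` data.frame.
#' @export
grid_search <- function(X, Y, groups, config = cigbls_config(),
                        lambda_grid = 10^seq(-4, 1),
                        gamma_grid = 10^seq(-4, 0),
                        beta_grid = c(0, 0.01, 0.05),
                        val_frac = 0.2, seed = 1L) {
  X <- check_matrix(X); Y <- check_matrix(Y)
  ids <- unique(groups)
  split <- stratified_batch_split(ids, rep(1L, length(ids)),
                                  train_frac = 1 - val_frac, seed = seed)
  fit_rows <- groups %in% split$train   # the smaller "test" side validates
  val_rows <- !fit_rows
  combos <- expand.grid(lambda = lambda_grid, gamma = gamma_grid,
                        beta = beta_grid, KEEP.OUT.ATTRS = FALSE)
  combos$val_rmse <- NA_real_
  for (i in seq_len(nrow(combos))) {
    cfg <- config
    cfg$lambda_reg <- combos$lambda[i]
    cfg$gamma <- combos$gamma[i]
    cfg$beta <- combos$beta[i]
    fit <- fit_cigbls(X[fit_rows, , drop = FALSE],
                      Y[fit_rows, , drop = FALSE], cfg)
    pred <- predict(fit, X[val_rows, , drop = FALSE])
    combos$val_rmse[i] <- compute_metrics(Y[val_rows, 1L], pred[, 1L])$rmse
  }
  ord <- order(combos$val_rmse, combos$beta, -combos$lambda)
  best_row <- combos[ord[1L], ]
  best <- config
  best$lambda_reg <- best_row$lambda
  best$gamma <- best_row$gamma
  best$beta <- best_row$beta
  list(best = best, best_rmse = best_row$val_rmse, results = combos)
}

#' Component ablation: full model and its three reductions
#'
#' Fits, with identical seed and node budget, the full model, the model
#' without anchor-graph regularization (`beta = 0`), the model without
#' channel independence (fully connected mapping + global anchors), and the
#' baseline with both removed (K-Means RBF BLS), and evaluates each on the
#' test design.
#'
#' @param train,test lists with `X` and `y` (e.g. sides of
#'   [build_design()]).
#' @param config the full-model [cigbls_config()].
#' @return A data.frame with one row per variant: rmse, mae, r2,
#'   train_time_s.
#' @export
run_ablation <- function(train, test, config = cigbls_config()) {
  variants <- list(
    `CI-GBLS`    = list(ci = TRUE, beta = config$beta),
    `w/o Graph`  = list(ci = TRUE, beta = 0),
    `w/o CI`     = list(ci = FALSE, beta = config$beta),
    `K-BLS`      = list(ci = FALSE, beta = 0))
  rows <- lapply(names(variants), function(nm) {
    v <- variants[[nm]]
    cfg <- config
    cfg$channel_independent <- v$ci
    cfg$beta <- v$beta
    fit <- fit_cigbls(train$X, as.matrix(train$y), cfg)
    m <- compute_metrics(test$y, predict(fit, test$X)[, 1L])
    data.frame(variant = nm, rmse = m$rmse, mae = m$mae, r2 = m$r2,
               train_time_s = fit$train_time_s)
  })
  do.call(rbind, rows)
}

#' Sensitivity of test RMSE to the manifold strength beta
#'
#' The feature maps, anchors and regularizer pieces do not depend on
#' `beta`, so they are built once and only the closed-form solve is
#' repeated per grid point — identical randomness across the sweep.
#'
#' @param train,test lists with `X` and `y`.
#' @param config base [cigbls_config()].
#' @param beta_grid values to sweep (default log grid over `[1e-6, 10]`).
#' @return A data.frame with `beta`, `rmse`, `mae`, `r2`.
#' @export
beta_sensitivity <- function(train, test, config = cigbls_config(),
                             beta_grid = 10^seq(-6, 1, by = 0.5)) {
  X <- check_matrix(train$X); Y <- as.matrix(train$y)
  fs <- cigbls_feature_stage(X, config)
  m_k <- if (config$channel_independent) config$anchors_per_channel
         else config$anchors_per_channel * ncol(X)
  anchors <- fit_channel_anchors(fs$Z, fs$layout, m_k, config$gamma,
                                 seed = sub_seed(config$seed, 2L),
                                 iters = config$kmeans_iters)
  enh <- rbf_enhance(fs$Z, fs$layout, anchors)
  A <- assemble_state(fs$Z, enh$H, config$xi_scale, fs$layout, enh$layout)
  reg <- build_anchor_regularizer(enh$H, 0)
  fs_te <- cigbls_feature_stage(check_matrix(test$X), config, maps = fs$maps)
  enh_te <- rbf_enhance(fs_te$Z, fs_te$layout, anchors)
  A_te <- cbind(fs_te$Z, config$xi_scale * enh_te$H)
  rows <- lapply(beta_grid, function(b) {
    W <- solve_manifold(A, Y, config$lambda_reg, reg, beta = b)
    m <- compute_metrics(test$y, predict_state(A_te, W)[, 1L])
    data.frame(beta = b, rmse = m$rmse, mae = m$mae, r2 = m$r2)
  })
  do.call(rbind, rows)
}
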