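# Channel-independent feature mapping, per-channel K-Means anchors, RBF
# enhancement nodes, and state-matrix assembly.
#
# Each input variable gets its own physically isolated mapping channel:
# a per-channel random linear map produces that channel's feature nodes, and
# per-channel anchors (K-Means centers in the channel's feature space) define
# RBF enhancement nodes. Cross-variable coupling is recovered only by the
# shared output weights.

#' Initialize per-channel random feature maps
#'
#' One `1 x nodes_per_channel` random map per input variable. Every channel
#' uses the identical hyperparameters but draws its weights from its own
#' sub-stream of the master seed, so adding a channel never perturbs the
#' randomness of the others.
#'
#' @param n_channels number of input variables M.
#' @param nodes_per_channel feature nodes per channel (total `L_f =
#'   M * nodes_per_channel`).
#' @param weight_init_range uniform draw interval for weights and biases.
#' @param seed master seed.
#' @return An object of class `channel_maps`: a list of RandomMaps plus the
#'   column-to-channel `layout`.
#' @export
init_channel_maps <- function(n_channels, nodes_per_channel = 10L,
                              weight_init_range = c(-1, 1), seed = 1L) {
  n_channels <- check_count(n_channels)
  nodes_per_channel <- check_count(nodes_per_channel)
  lo <- weight_init_range[1]; hi <- weight_init_range[2]
  maps <- lapply(seq_len(n_channels), function(i) {
    with_seed(sub_seed(seed, i), list(
      weights = matrix(runif(nodes_per_channel, lo, hi), 1L,
                       nodes_per_channel),
      bias = runif(nodes_per_channel, lo, hi)))
  })
  structure(list(maps = maps, n_channels = n_channels,
                 nodes_per_channel = nodes_per_channel,
                 layout = rep(seq_len(n_channels), each = nodes_per_channel)),
            class = "channel_maps")
}

#' Channel-independent feature mapping
#'
#' Maps each input variable through its own channel,
#' `Z_i = phi(x_i W_i + b_i)`, and concatenates the channels column-wise.
#' No weights are shared across channels, so perturbing variable `j` can only
#' change the columns belonging to channel `j`.
#'
#' @param X input matrix (samples x M).
#' @param maps a `channel_maps` object with M channels.
#' @param activation "linear" (default) or "tanh".
#' @return A list with the feature-node matrix `Z` (samples x L_f) and the
#'   integer `layout` giving the owning channel of every column.
#' @export
ci_feature_map <- function(X, maps, activation = "linear") {
  X <- check_matrix(X)
  if (ncol(X) != maps$n_channels)
    stop_invalid("X has ", ncol(X), " variables but maps expect ",
                 maps$n_channels)
  act <- activation_fun(activation)
  Z <- do.call(cbind, lapply(seq_len(maps$n_channels), function(i)
    apply_random_map(X[, i, drop = FALSE], maps$maps[[i]], act)))
  list(Z = Z, layout = maps$layout)
}

#' Fit per-channel K-Means anchors on the feature nodes
#'
#' Runs K-Means independently per channel, on that channel's feature-node
#' columns only, with k-means++ initialization, a capped number of Lloyd
#' iterations and one restart. Channels with fewer distinct points than
#' requested anchors get fewer anchors (with a warning). Anchors are fitted
#' on training data only and frozen afterwards.
#'
#' @param Z feature-node matrix from [ci_feature_map()].
#' @param layout column-to-channel assignment of `Z`.
#' @param anchors_per_channel anchors `m_k` per channel; the total anchor
#'   count equals the total number of enhancement nodes.
#' @param gamma RBF width used later by [rbf_enhance()]; stored here so the
#'   anchor set is self-describing.
#' @param seed master seed (per-channel sub-streams).
#' @param iters Lloyd iteration cap.
#' @return An object of class `anchor_set`.
#' @export
fit_channel_anchors <- function(Z, layout, anchors_per_channel = 10L,
                                gamma = 0.1, seed = 1L, iters = 100L) {
  Z <- check_matrix(Z)
  if (length(layout) != ncol(Z))
    stop_invalid("layout length must equal ncol(Z)")
  if (gamma < 0) stop_invalid("gamma must be >= 0")
  channels <- sort(unique(layout))
  anchors <- lapply(seq_along(channels), function(j) {
    cols <- which(layout == channels[j])
    km <- kmeans_fit(Z[, cols, drop = FALSE], anchors_per_channel,
                     iters = iters, seed = sub_seed(seed, 100000L + j))
    km$centers
  })
  names(anchors) <- as.character(channels)
  structure(list(anchors = anchors, channels = channels, gamma = gamma,
                 anchors_per_channel = check_count(anchors_per_channel),
                 seed = as.integer(seed)),
            class = "anchor_set")
}

#' RBF enhancement nodes from channel anchors
#'
#' For each channel the enhancement block is
#' `H[i, k] = exp(-gamma * ||z_i - u_k||^2)` over that channel's anchors;
#' blocks are concatenated in channel order. Entries lie in `(0, 1]`.
#'
#' @param Z feature-node matrix.
#' @param layout column-to-channel assignment used when the anchors were fit.
#' @param anchors an `anchor_set`.
#' @return A list with the enhancement matrix `H` and its column `layout`.
#' @export
rbf_enhance <- function(Z, layout, anchors) {
  Z <- check_matrix(Z)
  if (length(layout) != ncol(Z))
    stop_invalid("layout length must equal ncol(Z)")
  if (!setequal(unique(layout), anchors$channels))
    stop_invalid("layout channels do not match the fitted anchor set")
  blocks <- lapply(seq_along(anchors$channels), function(j) {
    ch <- anchors$channels[j]
    U <- anchors$anchors[[as.character(ch)]]
    Zc <- Z[, layout == ch, drop = FALSE]
    if (ncol(Zc) != ncol(U))
      stop_invalid("channel ", ch, " width differs from its anchors")
    exp(-anchors$gamma * sqdist_cross(Zc, U))
  })
  H <- do.call(cbind, blocks)
  h_layout <- rep(anchors$channels, vapply(blocks, ncol, 0L))
  list(H = H, layout = h_layout)
}

#' Assemble the system state matrix
#'
#' `A = [Z_f | xi * H]`, with bookkeeping of which column is a feature or an
#' enhancement node and which channel owns it.
#'
#' @param Z feature-node matrix. @param H enhancement matrix.
#' @param xi_scale scaling of the enhancement block.
#' @param z_layout,h_layout channel layouts of the two blocks.
#' @return An object of class `state_matrix` with `values`, `kind`
#'   ("feature"/"enhancement" per column), `channel`, and the node counts.
#' @export
assemble_state <- function(Z, H, xi_scale = 0.5,
                           z_layout = NULL, h_layout = NULL) {
  Z <- check_matrix(Z); H <- check_matrix(H)
  if (nrow(Z) != nrow(H)) stop_invalid("Z and H must have equal row counts")
  structure(list(
    values = cbind(Z, xi_scale * H),
    kind = rep(c("feature", "enhancement"), c(ncol(Z), ncol(H))),
    channel = c(z_layout %||% rep(NA_integer_, ncol(Z)),
                h_layout %||% rep(NA_integer_, ncol(H))),
    n_feature_nodes = ncol(Z), n_enh_nodes = ncol(H),
    xi_scale = xi_scale), class = "state_matrix")
}

# Accept either a raw matrix or a state_matrix wherever A is consumed.
state_values <- function(A) if (inherits(A, "state_matrix")) A$values else check_matrix(A)
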