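# Deterministic Lloyd K-Means with k-means++ seeding.
#
# Written here (rather than calling stats::kmeans) because the anchor fitting
# contract requires k-means++ initialization, a hard iteration cap, a single
# restart, farthest-point re-seeding of empty clusters, and bit-reproducible
# behaviour under a sub-seed per channel.

# Squared Euclidean distances between rows of X (n x d) and rows of C (k x d).
sqdist_cross <- function(X, C) {
  xx <- rowSums(X * X)
  cc <- rowSums(C * C)
  d2 <- outer(xx, cc, "+") - 2 * X %*% t(C)
  d2[d2 < 0] <- 0
  d2
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- X[idx, ]
  if (k == 1L) return(centers)
  d2 <- sqdist_cross(X, centers[1L, , drop = FALSE])[, 1L]
  for (j in 2:k) {
    tot <- sum(d2)
    if (tot <= 0) { # all remaining points coincide with a chosen center
      idx <- sample.int(n, 1L)
    } else {
      idx <- sample.int(n, 1L, prob = d2 / tot)
    }
    centers[j, ] <- X[idx, ]
    d2 <- pmin(d2, sqdist_cross(X, centers[j, , drop = FALSE])[, 1L])
  }
  centers
}

#' K-Means clustering with k-means++ seeding
#'
#' Plain Lloyd iterations with k-means++ initialization, a fixed iteration
#' cap and a single restart. Empty clusters are re-seeded at the point
#' farthest from its assigned center. Fully deterministic given `seed`.
#'
#' @param X numeric matrix, one observation per row.
#' @param k number of clusters requested. If `X` has fewer distinct rows than
#'   `k`, the number of clusters is reduced with a warning.
#' @param iters maximum number of Lloyd iterations (default 100).
#' @param seed integer seed controlling initialization.
#' @return A list with `centers` (k x d matrix), `cluster` (assignment per
#'   row) and `iterations` used.
#' @export
kmeans_fit <- function(X, k, iters = 100L, seed = 1L) {
  X <- check_matrix(X)
  k <- check_count(k)
  iters <- check_count(iters)
  n_distinct <- nrow(unique(X))
  if (n_distinct < k) {
    warning(sprintf("only %d distinct points; reducing clusters from %d",
                    n_distinct, k), call. = FALSE)
    k <- n_distinct
  }
  with_seed(seed, {
    centers <- kmeanspp_init(X, k)
    assign_prev <- rep(-1L, nrow(X))
    it <- 0L
    repeat {
      it <- it + 1L
      d2 <- sqdist_cross(X, centers)
      assign_cur <- max.col(-d2, ties.method = "first")
      # re-seed empty clusters at the globally farthest point
      for (j in seq_len(k)) {
        if (!any(assign_cur == j)) {
          far <- which.max(d2[cbind(seq_len(nrow(X)), assign_cur)])
          centers[j, ] <- X[far, ]
          assign_cur[far] <- j
        }
      }
      if (identical(assign_cur, assign_prev) || it >= iters) {
        for (j in seq_len(k))
          centers[j, ] <- colMeans(X[assign_cur == j, , drop = FALSE])
        return(list(centers = centers, cluster = assign_cur, iterations = it))
      }
      for (j in seq_len(k))
        centers[j, ] <- colMeans(X[assign_cur == j, , drop = FALSE])
      assign_prev <- assign_cur
    }
  })
}
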