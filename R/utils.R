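# Internal helpers: argument checking, seed sub-streams, stable solves.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(structure(class = c("cigbls_invalid_argument", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_matrix <- function(X, name = deparse(substitute(X))) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (!is.numeric(X)) stop_invalid(name, " must be numeric")
  if (any(!is.finite(X))) stop_invalid(name, " contains non-finite values")
  X
}

check_count <- function(x, name = deparse(substitute(x)), min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    stop_invalid(name, " must be a single integer >= ", min)
  as.integer(x)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' All randomness in the package flows from one integer seed. Independent
#' consumers (channels, batches, restarts) each draw from their own sub-stream
#' whose seed is a deterministic mix of the master seed and a stream index, so
#' adding a channel or batch never shifts the randomness of the others.
#' Results stay inside the 32-bit signed integer range `set.seed()` accepts.
#'
#' @param master single integer master seed.
#' @param index nonnegative integer stream index.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
sub_seed <- function(master, index) {
  master <- as.numeric(master); index <- as.numeric(index)
  # Knuth-style multiplicative mix, carried out in double precision where
  # 2^31-1 arithmetic is exact.
  m <- 2147483647
  s <- (master %% m) * 48271 %% m
  s <- (s + (index %% m) * 16807 + 12345) %% m
  as.integer(s)
}

# Evaluate `expr` under a given RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Moore-Penrose pseudo-inverse via SVD; used only as a rank-deficiency
# fallback for the closed-form solvers.
pinv <- function(M, tol = NULL) {
  s <- svd(M)
  tol <- tol %||% (max(dim(M)) * max(s$d) * .Machine$double.eps)
  pos <- s$d > tol
  if (!any(pos)) return(matrix(0, ncol(M), nrow(M)))
  s$v[, pos, drop = FALSE] %*% ((1 / s$d[pos]) * t(s$u[, pos, drop = FALSE]))
}

# Solve the SPD system M x = B by Cholesky; fall back to the pseudo-inverse
# with a warning when M is numerically rank-deficient.
solve_spd <- function(M, B, context = "linear system") {
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) {
    warning(sprintf("%s is numerically rank-deficient; using pseudo-inverse",
                    context), call. = FALSE)
    return(pinv(M) %*% B)
  }
  backsolve(ch, forwardsolve(t(ch), B))
}

frob <- function(M) sqrt(sum(M * M))
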