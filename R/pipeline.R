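# Multi-rate preprocessing for batch-process soft sensing: assay-delay
# alignment, sparse-label interpolation, sliding windows, stratified batch
# splits, train-only min-max scaling, and the standard regression metrics.

#' Construct a process batch
#'
#' Container for one batch of a multivariate fed-batch process: a
#' high-frequency table of process variables plus a sparse series of offline
#' quality assays.
#'
#' @param batch_id identifier. @param time_min strictly increasing process
#'   timestamps in minutes. @param X numeric T x M matrix of process
#'   variables. @param quality data.frame with `time_min` and `value` for
#'   the sparse assays. @param mode control-mode stratum label.
#' @param truth optional data.frame with the dense ground-truth quality
#'   (available from simulation only).
#' @return An object of class `process_batch`.
#' @export
process_batch <- function(batch_id, time_min, X, quality, mode = 1L,
                          truth = NULL) {
  X <- check_matrix(X)
  if (length(time_min) != nrow(X))
    stop_invalid("time_min length must equal nrow(X)")
  if (any(diff(time_min) <= 0))
    stop_invalid("time_min must be strictly increasing")
  structure(list(batch_id = batch_id, time_min = as.numeric(time_min),
                 X = X, quality = quality, mode = mode, truth = truth),
            class = "process_batch")
}

batch_dt <- function(batch) stats::median(diff(batch$time_min))

#' Align assay labels with process inputs
#'
#' Offline assays carry an analytical delay: a result recorded at time `t`
#' reflects the sample drawn at `t - delay`. Shifting the quality timestamps
#' back by `delay_minutes` aligns each assay with the process inputs at its
#' draw time. Delays that are not a multiple of the process sampling
#' interval are rounded to the nearest multiple with a warning; shifted
#' assays falling before the start of the batch are dropped (missing).
#'
#' @param batch a `process_batch`.
#' @param delay_minutes analytical delay (240 for a 4-h assay at 12-min
#'   sampling, i.e. 20 samples). May be negative to undo a shift.
#' @return The batch with shifted quality timestamps.
#' @export
shift_target <- function(batch, delay_minutes) {
  dt <- batch_dt(batch)
  if (abs(delay_minutes %% dt) > 1e-9 &&
      abs(dt - delay_minutes %% dt) > 1e-9) {
    rounded <- round(delay_minutes / dt) * dt
    warning(sprintf("delay %g min is not a multiple of the %g-min sampling interval; rounding to %g",
                    delay_minutes, dt, rounded), call. = FALSE)
    delay_minutes <- rounded
  }
  q <- batch$quality
  q$time_min <- q$time_min - delay_minutes
  keep <- q$time_min >= batch$time_min[1] - 1e-9
  batch$quality <- q[keep, , drop = FALSE]
  batch
}

#' Reconstruct a dense quality series by linear interpolation
#'
#' Linearly interpolates between assay points on the high-frequency process
#' grid; before the first and after the last assay the nearest assay value
#' is held (boundary padding). Quality variables in fermentation drift
#' slowly, so the piecewise-linear trend is a reasonable stand-in for the
#' unobserved values. A batch with fewer than two assays is constant-filled
#' with a warning.
#'
#' @param batch a `process_batch` (already delay-aligned).
#' @return Numeric vector of quality values on `batch$time_min`.
#' @export
interpolate_labels <- function(batch) {
  q <- batch$quality
  if (nrow(q) < 2L) {
    warning("fewer than 2 assays; constant fill", call. = FALSE)
    return(rep(if (nrow(q)) q$value else NA_real_, length(batch$time_min)))
  }
  stats::approx(q$time_min, q$value, xout = batch$time_min, rule = 2)$y
}

#' Sliding-window design rows for one batch
#'
#' Each output row is the flattened window of the M process variables over
#' the `window_len` samples ending at time t (columns ordered
#' `var1_lag(w-1) ... var1_lag0, var2_lag(w-1) ...`, so every lagged column
#' can act as its own channel downstream), with target equal to the dense
#' quality at t. Windows never cross batch boundaries.
#'
#' @param batch a `process_batch`. @param window_len window length in
#'   samples (default 1: current-time snapshot). @param stride step between
#'   consecutive windows.
#' @param y optional precomputed dense target (defaults to
#'   [interpolate_labels()] on the batch).
#' @return A list with `X`, `y`, `time_min` (window-end times) and
#'   `batch_id` per row.
#' @export
make_windows <- function(batch, window_len = 1L, stride = 1L, y = NULL) {
  window_len <- check_count(window_len)
  stride <- check_count(stride)
  y <- y %||% interpolate_labels(batch)
  Tn <- nrow(batch$X); M <- ncol(batch$X)
  if (Tn < window_len) stop_invalid("batch shorter than window")
  ends <- seq.int(window_len, Tn, by = stride)
  Xw <- matrix(NA_real_, length(ends), M * window_len)
  for (r in seq_along(ends)) {
    idx <- (ends[r] - window_len + 1L):ends[r]
    Xw[r, ] <- as.vector(batch$X[idx, , drop = FALSE]) # column-major: var-blocks
  }
  vn <- colnames(batch$X) %||% paste0("var", seq_len(M))
  colnames(Xw) <- as.vector(vapply(vn, function(v)
    paste0(v, "_lag", rev(seq_len(window_len)) - 1L), character(window_len)))
  list(X = Xw, y = y[ends], time_min = batch$time_min[ends],
       batch_id = rep(batch$batch_id, length(ends)))
}

#' Stratified batch-level train/test split
#'
#' Splits at batch granularity so no sample of a batch appears in both
#' sets; within each control-mode stratum, `round(train_frac * n)` batches
#' (half-up rounding) go to training. Deterministic under `seed`.
#'
#' @param batch_ids vector of batch identifiers.
#' @param strata stratum label per batch (same length); a single common
#'   label reduces to a plain batch split.
#' @param train_frac fraction of batches per stratum assigned to training.
#' @param seed integer seed.
#' @return A list with `train` and `test` id vectors.
#' @export
stratified_batch_split <- function(batch_ids, strata, train_frac = 0.8,
                                   seed = 1L) {
  if (length(strata) != length(batch_ids))
    stop_invalid("strata must label every batch")
  if (train_frac <= 0 || train_frac >= 1)
    stop_invalid("train_frac must be in (0, 1)")
  train <- character(0); test <- character(0)
  for (s in sort(unique(strata))) {
    ids <- batch_ids[strata == s]
    n_tr <- floor(train_frac * length(ids) + 0.5)
    n_tr <- max(1L, min(length(ids) - 1L, n_tr))
    perm <- with_seed(sub_seed(seed, match(s, sort(unique(strata)))),
                      sample(ids))
    train <- c(train, as.character(perm[seq_len(n_tr)]))
    test <- c(test, as.character(perm[-seq_len(n_tr)]))
  }
  list(train = train, test = test)
}

#' Fit min-max scaling parameters
#'
#' Per-column min and max, to be fitted on training rows exclusively.
#' Constant columns are flagged (they map to 0) with a warning.
#'
#' @param X training design matrix.
#' @return A list with `min`, `range`, `constant`.
#' @export
minmax_fit <- function(X) {
  X <- check_matrix(X)
  mn <- apply(X, 2L, min); mx <- apply(X, 2L, max)
  const <- mx - mn <= 0
  if (any(const))
    warning(sprintf("%d constant column(s) map to 0", sum(const)),
            call. = FALSE)
  list(min = mn, range = ifelse(const, 1, mx - mn), constant = const)
}

#' Apply fitted min-max scaling
#'
#' Training columns map to `[0, 1]`; test values may fall outside (no
#' clipping), mirroring deployment where new batches can exceed the
#' historical envelope.
#'
#' @param X matrix to scale. @param params from [minmax_fit()].
#' @return Scaled matrix.
#' @export
minmax_apply <- function(X, params) {
  X <- check_matrix(X)
  if (ncol(X) != length(params$min)) stop_invalid("column count mismatch")
  Xs <- sweep(sweep(X, 2L, params$min, "-"), 2L, params$range, "/")
  Xs[, params$constant] <- 0
  Xs
}

#' Regression metrics: RMSE, MAE, R-squared
#'
#' `RMSE = sqrt(mean((y - yhat)^2))`, `MAE = mean(|y - yhat|)`,
#' `R2 = 1 - SSE/SST` with `SST = sum((y - mean(y))^2)`.
#'
#' @param y observed values. @param y_hat predictions.
#' @return A list with `rmse`, `mae`, `r2`.
#' @export
compute_metrics <- function(y, y_hat) {
  y <- as.numeric(y); y_hat <- as.numeric(y_hat)
  if (length(y) != length(y_hat)) stop_invalid("length mismatch")
  e <- y - y_hat
  sst <- sum((y - mean(y))^2)
  list(rmse = sqrt(mean(e^2)), mae = mean(abs(e)),
       r2 = 1 - sum(e^2) / sst)
}

#' Welch's t-test on repeated-run metrics
#'
#' Reporting utility for comparing two models' metric samples over repeated
#' seeded runs (unequal variances).
#'
#' @param a,b numeric metric samples.
#' @return The `htest` object from [stats::t.test()].
#' @export
welch_test <- function(a, b) stats::t.test(a, b, var.equal = FALSE)

#' Build aligned, windowed, scaled train/test designs from a dataset
#'
#' Runs the full preprocessing chain per batch — delay alignment, label
#' interpolation, sliding windows — concatenates batches, then fits min-max
#' scaling on the training rows only and applies it to both sets.
#'
#' @param dataset a `process_dataset` (see [simulate_dataset()] /
#'   [read_process_csv()]).
#' @param split list with `train`/`test` batch-id vectors, e.g. from
#'   [stratified_batch_split()].
#' @param delay_minutes analytical assay delay to remove.
#' @param window_len,stride sliding-window geometry.
#' @param order `"shift_first"` (align assays, then interpolate; default)
#'   or `"interpolate_first"` (interpolate the raw assay series, then shift
#'   the dense series).
#' @return A list with `train` and `test`, each holding `X` (scaled), `y`,
#'   `groups` (batch id per row), `time_min`; plus `scaler`.
#' @export
build_design <- function(dataset, split, delay_minutes = 240,
                         window_len = 1L, stride = 1L,
                         order = c("shift_first", "interpolate_first")) {
  order <- match.arg(order)
  one_side <- function(ids) {
    parts <- lapply(ids, function(id) {
      b <- dataset$batches[[as.character(id)]]
      if (is.null(b)) stop_invalid("unknown batch id ", id)
      if (order == "shift_first") {
        make_windows(shift_target(b, delay_minutes), window_len, stride)
      } else {
        y <- interpolate_labels(b)
        k <- as.integer(round(delay_minutes / batch_dt(b)))
        # dense series shifted back by k samples; tail padded with last value
        y <- if (k > 0) c(y[-seq_len(k)], rep(y[length(y)], k)) else y
        make_windows(b, window_len, stride, y = y)
      }
    })
    list(X = do.call(rbind, lapply(parts, `[[`, "X")),
         y = unlist(lapply(parts, `[[`, "y")),
         groups = unlist(lapply(parts, `[[`, "batch_id")),
         time_min = unlist(lapply(parts, `[[`, "time_min")))
  }
  tr <- one_side(split$train); te <- one_side(split$test)
  scaler <- minmax_fit(tr$X)
  tr$X <- minmax_apply(tr$X, scaler)
  te$X <- minmax_apply(te$X, scaler)
  list(train = tr, test = te, scaler = scaler)
}
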