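# Seeded generator of fed-batch penicillin-like process data.
#
# Deliberately NOT a mechanistic fermentation simulator: it reproduces only
# the statistical features the soft-sensor method exploits — multi-rate
# sampling (12-min process variables, 12-h assays with a 4-h analytical
# delay), slow monotone quality drift, nonlinear multivariate coupling
# through a small set of latent states, channel-heterogeneous dynamics
# (per-variable lags, nonlinearities and pure-distractor channels), several
# control-mode strata, and batch-to-batch variability.

#' Simulation configuration
#'
#' Defaults emulate the structure of the 100-batch industrial penicillin
#' benchmark regime this package targets: 90 non-faulty batches of ~230 h,
#' 18 process variables every 12 min, penicillin concentration assayed
#' every 12 h with a 4-h analytical delay, three control-mode strata.
#'
#' @param n_batches number of batches.
#' @param duration_h batch duration in hours.
#' @param process_dt_min process sampling interval in minutes.
#' @param quality_dt_h assay interval in hours.
#' @param n_vars number of observed process variables.
#' @param assay_delay_h analytical delay of the offline assay in hours.
#' @param noise_sd relative sensor noise (fraction of each variable's
#'   signal SD); the offline assay error uses the same knob, at
#'   `7.5 * noise_sd` in concentration units (default 0.15 g/L).
#' @param batch_variability_sd log-scale SD of the batch-level random
#'   effects on kinetic and gain parameters (also scales operator-mode feed
#'   adjustments).
#' @param control_modes number of control-mode strata.
#' @param seed master seed; each batch draws from its own sub-stream.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_batches = 90L, duration_h = 230, process_dt_min = 12,
                       quality_dt_h = 12, n_vars = 18L, assay_delay_h = 4,
                       noise_sd = 0.02, batch_variability_sd = 0.05,
                       control_modes = 3L, seed = 1L) {
  cfg <- list(n_batches = check_count(n_batches), duration_h = duration_h,
              process_dt_min = process_dt_min, quality_dt_h = quality_dt_h,
              n_vars = check_count(n_vars), assay_delay_h = assay_delay_h,
              noise_sd = noise_sd,
              batch_variability_sd = batch_variability_sd,
              control_modes = check_count(control_modes),
              seed = as.integer(seed))
  if (cfg$duration_h / cfg$quality_dt_h < 2)
    stop_invalid("duration must allow at least 2 assays")
  if (cfg$noise_sd < 0 || cfg$batch_variability_sd < 0)
    stop_invalid("noise SDs must be >= 0")
  structure(cfg, class = "sim_config")
}

lag_series <- function(v, k) if (k <= 0) v else c(rep(v[1L], k), v[seq_len(length(v) - k)])

# Observed-variable recipes: each maps the latent trajectories to one
# sensor channel. Generic industrial names; heterogeneous nonlinearities.
var_recipes <- function() list(
  feed_rate    = function(l) l$F,
  paa_flow     = function(l) 0.3 * l$F + 0.02,
  temp         = function(l) 25 + 0.8 * tanh(1.5 * l$act),
  pH           = function(l) 6.5 - 0.4 * l$S / (1 + l$S) + 0.1 * tanh(l$P / 10),
  dO2          = function(l) 100 - 55 * l$act / (0.3 + l$act),
  offgas_co2   = function(l) 0.5 + 3 * l$act,
  offgas_o2    = function(l) 20.9 - 2.5 * l$act,
  biomass_cap  = function(l) sqrt(pmax(l$Xb, 0)),
  substrate_ir = function(l) log1p(pmax(l$S, 0)),
  viscosity    = function(l) 0.5 * l$Xb + 0.05 * l$P,
  agitator_pw  = function(l) rep(1, length(l$F)),          # pure distractor
  coolant_flow = function(l) 2 + 0.08 * l$Xb + 0.5 * tanh(l$act),
  base_flow    = function(l) 0.1 + 0.05 * l$S / (0.5 + l$S),
  vessel_pres  = function(l) rep(1.2, length(l$F)),        # pure distractor
  o2_uptake    = function(l) 1.8 * l$act / (0.2 + l$act),
  co2_evolve   = function(l) 2.1 * l$act + 0.02 * l$P,
  turbidity    = function(l) l$Xb^0.7,
  perm_probe   = function(l) 0.3 * l$P + 0.1 * sqrt(pmax(l$Xb, 0)))

#' Simulate one fed-batch
#'
#' Latent biomass/substrate/product follow a simple Monod-type fed-batch
#' model integrated by forward Euler: logistic biomass growth with Monod
#' substrate limitation, substrate depletion against a mode-dependent feed
#' profile, and product formation proportional to biomass with substrate
#' limitation and product-inhibition saturation (hence monotone
#' non-decreasing quality). Observed variables are lagged nonlinear
#' mixtures of the latents with batch-level gain effects and relative
#' Gaussian sensor noise; two channels are pure distractors. The assay
#' series subsamples the product every `quality_dt_h` hours, adds assay
#' noise, and is timestamped at draw time plus the analytical delay.
#'
#' @param cfg a [sim_config()]. @param batch_seed integer seed for this
#'   batch's sub-stream. @param mode control mode in
#'   `1..cfg$control_modes`: 1 = recipe-driven stepped feed, 2 = operator
#'   feed with drift and discrete adjustments, 3 = feedback control toward
#'   a substrate setpoint.
#' @param batch_id identifier for the resulting batch.
#' @return A [process_batch()] whose `truth` holds the dense noise-free
#'   product concentration.
#' @export
simulate_batch <- function(cfg, batch_seed, mode = 1L, batch_id = "b1") {
  dt <- cfg$process_dt_min / 60
  t_h <- seq(0, cfg$duration_h, by = dt)
  Tn <- length(t_h)
  with_seed(batch_seed, {
    bv <- cfg$batch_variability_sd
    eff <- exp(stats::rnorm(4L, 0, bv))     # kinetic/gain random effects
    mu_max <- 0.11 * eff[1L]; Ks <- 0.5; Xmax <- 35
    Yxs <- 0.45 * eff[2L]; ms <- 0.015
    kp <- 0.09 * eff[3L]; Kps <- 0.05; Psat <- 30
    feed_gain <- 0.08 * eff[4L]
    # mode-dependent feed profile
    n_adj <- max(1L, as.integer(cfg$duration_h / 24))
    adj <- stats::rnorm(n_adj, 0, bv)       # operator adjustments (mode 2)
    Xb <- S <- P <- Fv <- numeric(Tn)
    Xb[1L] <- 0.3; S[1L] <- 15; P[1L] <- 0; Fcur <- 0
    mode_eff <- min(as.integer(mode), 4L)
    for (i in seq_len(Tn)) {
      ti <- t_h[i]
      Fcur <- switch(mode_eff,
        { if (ti < 0.1 * cfg$duration_h) 0
          else feed_gain * (1 + 0.5 * floor(3 * ti / cfg$duration_h)) },
        { j <- min(n_adj, 1L + as.integer(ti / 24))
          max(0, feed_gain * (1 + 0.3 * sin(2 * pi * ti / cfg$duration_h)) *
                (1 + adj[j])) },
        { if (i == 1L) 0
          else max(0, min(0.12, Fcur + 0.25 * dt * (0.8 - S[i - 1L]))) },
        feed_gain)                           # modes > 3: constant feed
      Fv[i] <- Fcur
      if (i < Tn) {
        mu <- mu_max * S[i] / (Ks + S[i])
        dXb <- mu * Xb[i] * (1 - Xb[i] / Xmax)
        dS <- Fv[i] - mu * Xb[i] / Yxs - ms * Xb[i]
        dP <- kp * Xb[i] * S[i] / (Kps + S[i]) / (1 + P[i] / Psat)
        Xb[i + 1L] <- max(Xb[i] + dt * dXb, 0)
        S[i + 1L] <- max(S[i] + dt * dS, 0)
        P[i + 1L] <- P[i] + dt * dP
      }
    }
    lat <- list(Xb = Xb, S = S, P = P, F = Fv,
                act = mu_max * S / (Ks + S) * Xb / 10)
    recipes <- var_recipes()
    lags <- c(0L, 1L, 2L, 5L, 10L)           # heterogeneous channel lags
    X <- matrix(NA_real_, Tn, cfg$n_vars)
    vn <- character(cfg$n_vars)
    for (j in seq_len(cfg$n_vars)) {
      r <- ((j - 1L) %% length(recipes)) + 1L
      v <- recipes[[r]](lat)
      v <- lag_series(v, lags[((j - 1L) %% length(lags)) + 1L])
      gain <- exp(stats::rnorm(1L, 0, bv))
      v <- gain * v
      v_sd <- stats::sd(v)
      if (v_sd == 0) v_sd <- 1   # distractor channels carry pure noise
      X[, j] <- v + stats::rnorm(Tn, 0, cfg$noise_sd * v_sd)
      vn[j] <- if (j <= length(recipes)) names(recipes)[r]
               else paste0(names(recipes)[r], "_", 1L + (j - 1L) %/% length(recipes))
    }
    colnames(X) <- vn
    draw_h <- seq(0, cfg$duration_h, by = cfg$quality_dt_h)
    assay <- P[match(round(draw_h / dt), round(t_h / dt))] +
      stats::rnorm(length(draw_h), 0, 7.5 * cfg$noise_sd)
    quality <- data.frame(time_min = (draw_h + cfg$assay_delay_h) * 60,
                          value = assay)
    process_batch(batch_id, t_h * 60, X, quality, mode = mode,
                  truth = data.frame(time_min = t_h * 60, value = P))
  })
}

#' Simulate a multi-batch dataset
#'
#' Batches are assigned to control modes in contiguous blocks (mode 1
#' first, then mode 2, ...), each batch simulated under its own sub-seed.
#'
#' @param cfg a [sim_config()].
#' @return An object of class `process_dataset`: named list of batches,
#'   `ids`, `modes`, the `cfg`, and a `manifest` of per-batch seeds.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  per_mode <- ceiling(cfg$n_batches / cfg$control_modes)
  modes <- rep(seq_len(cfg$control_modes), each = per_mode)[seq_len(cfg$n_batches)]
  ids <- sprintf("b%03d", seq_len(cfg$n_batches))
  seeds <- vapply(seq_len(cfg$n_batches), function(i) sub_seed(cfg$seed, i), 0L)
  batches <- lapply(seq_len(cfg$n_batches), function(i)
    simulate_batch(cfg, seeds[i], modes[i], ids[i]))
  names(batches) <- ids
  structure(list(batches = batches, ids = ids, modes = modes, cfg = cfg,
                 manifest = data.frame(batch_id = ids, mode = modes,
                                       seed = seeds)),
            class = "process_dataset")
}

#' Write a dataset to a long-format CSV
#'
#' One row per process time step with columns `batch_id`, `mode`,
#' `time_min`, the process variables, `quality` (blank except at assay
#' recording times) and, when available, `quality_truth`. Assays recorded
#' after the last process sample get their own rows with blank process
#' variables.
#'
#' @param dataset a `process_dataset`. @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_process_csv <- function(dataset, path) {
  rows <- lapply(dataset$batches, function(b) {
    df <- data.frame(batch_id = b$batch_id, mode = b$mode,
                     time_min = b$time_min, b$X, check.names = FALSE)
    df$quality <- NA_real_
    hit <- match(round(b$quality$time_min, 6), round(b$time_min, 6))
    inside <- !is.na(hit)
    df$quality[hit[inside]] <- b$quality$value[inside]
    if (any(!inside)) {
      extra <- df[rep(1L, sum(!inside)), ]
      extra[, !(names(extra) %in% c("batch_id", "mode", "time_min", "quality"))] <- NA_real_
      extra$time_min <- b$quality$time_min[!inside]
      extra$quality <- b$quality$value[!inside]
      df <- rbind(df, extra)
    }
    if (!is.null(b$truth))
      df$quality_truth <- b$truth$value[match(round(df$time_min, 6),
                                              round(b$truth$time_min, 6))]
    df
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a long-format process CSV
#'
#' Inverse of [write_process_csv()]; rows with blank process variables are
#' treated as assay-only records.
#'
#' @param path CSV path.
#' @return A `process_dataset` (without `cfg`/`manifest`).
#' @export
read_process_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- c("batch_id", "mode", "time_min", "quality", "quality_truth")
  var_cols <- setdiff(names(df), meta)
  ids <- unique(df$batch_id)
  batches <- lapply(ids, function(id) {
    d <- df[df$batch_id == id, , drop = FALSE]
    d <- d[order(d$time_min), , drop = FALSE]
    is_proc <- stats::complete.cases(d[, var_cols, drop = FALSE])
    q <- d[!is.na(d$quality), c("time_min", "quality")]
    names(q) <- c("time_min", "value")
    truth <- if ("quality_truth" %in% names(d)) {
      tr <- d[is_proc & !is.na(d$quality_truth), c("time_min", "quality_truth")]
      names(tr) <- c("time_min", "value"); tr
    }
    process_batch(id, d$time_min[is_proc],
                  as.matrix(d[is_proc, var_cols, drop = FALSE]),
                  q, mode = d$mode[1L], truth = truth)
  })
  names(batches) <- as.character(ids)
  modes <- vapply(batches, function(b) as.integer(b$mode), 0L)
  structure(list(batches = batches, ids = as.character(ids),
                 modes = unname(modes), cfg = NULL, manifest = NULL),
            class = "process_dataset")
}
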