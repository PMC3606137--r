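# Simulated experiments: Bernoulli spike trains for the eight bank
# neurons at every (task, C_dir, C_dep) cell, reduced per trial to the
# final integrated value via the closed-form decision weights.  Several
# model variants can be evaluated on *shared* spike trains (the spec for
# the exact gate/leak equivalence and for parameter sweeps), which the
# per-trial recursion in integrate_trial() reproduces to floating
# tolerance.

# Map the decision weights (over the integration window) onto the full
# trial grid: bin starting at tau contributes with the weight attached
# to its end time tau + step.
weights_on_grid <- function(wt, times, step) {
  n <- length(times)
  A_rel <- numeric(n)
  A_irr <- numeric(n)
  idx <- match(wt$tau - step, times)
  if (any(is.na(idx))) {
    stop("integration window is not covered by the trial grid",
         call. = FALSE)
  }
  A_rel[idx] <- wt$a_rel
  A_irr[idx] <- wt$a_irr
  cbind(A_rel, A_irr)
}

# 100-ms choice-probability bins as an indicator matrix over the grid.
cp_bin_matrix <- function(times, starts = seq(-100, 600, by = 100),
                          width = 100) {
  B <- vapply(starts, function(s) {
    as.numeric(times >= s & times < s + width)
  }, numeric(length(times)))
  colnames(B) <- starts
  B
}

# Core simulation over cells.  `weight_list` is a list of weight sets
# (one per model evaluated on the shared trains), each from
# integration_weights().  Returns one trials data frame per weight set
# plus (optionally) the shared per-trial 100-ms bin counts.
sim_experiment_core <- function(table, grid, weight_list,
                                trials_per_condition, seed,
                                keep_counts = FALSE,
                                tasks = c("direction", "depth"),
                                step = 1) {
  stopifnot(inherits(table, "population_rate_table"),
            trials_per_condition >= 1)
  grid <- sort(unique(grid))
  times <- table$tau
  nbin <- length(times)
  nt <- as.integer(trials_per_condition)
  cells <- expand.grid(task = tasks, c_dir = grid, c_dep = grid,
                       KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  ncell <- nrow(cells)
  seeds <- derive_seeds(seed, ncell)
  J <- length(weight_list)
  A <- lapply(weight_list, weights_on_grid, times = times, step = step)
  A_rel <- do.call(cbind, lapply(A, function(a) a[, 1]))  # nbin x J
  A_irr <- do.call(cbind, lapply(A, function(a) a[, 2]))
  B <- if (keep_counts) cp_bin_matrix(times) else NULL

  n_total <- ncell * nt
  I_all <- matrix(0, n_total, J)
  counts <- if (keep_counts) {
    array(0L, dim = c(n_total, 8L, ncol(B)),
          dimnames = list(NULL, paste0("n", 1:8), colnames(B)))
  } else NULL

  for (ci in seq_len(ncell)) {
    set.seed(seeds[ci])
    task <- cells$task[ci]
    R8 <- bank_rates(table, cells$c_dir[ci], cells$c_dep[ci], task)
    p <- pmin(R8 * step, 1)
    # relevant stream: i_dir in the direction task, i_dep in the depth task
    c_rel <- if (task == "direction") DIR_COEF else DEP_COEF
    c_irr <- if (task == "direction") DEP_COEF else DIR_COEF
    rows <- ((ci - 1L) * nt + 1L):(ci * nt)
    Icell <- matrix(0, nt, J)
    for (n in 1:8) {
      S <- matrix(runif(nt * nbin) < rep(p[, n], each = nt), nt, nbin)
      storage.mode(S) <- "double"
      M <- S %*% cbind(A_rel, A_irr)  # nt x 2J
      Icell <- Icell + c_rel[n] * M[, seq_len(J), drop = FALSE] +
        c_irr[n] * M[, J + seq_len(J), drop = FALSE]
      if (keep_counts) counts[rows, n, ] <- as.integer(S %*% B)
    }
    I_all[rows, ] <- Icell
  }

  # fair-coin tie break, one coin per trial shared across weight sets
  set.seed(seeds[1L] + 1L)
  coin <- runif(n_total) < 0.5

  base <- data.frame(
    task = rep(cells$task, each = nt),
    c_dir = rep(cells$c_dir, each = nt),
    c_dep = rep(cells$c_dep, each = nt),
    trial = rep(seq_len(nt), times = ncell),
    stringsAsFactors = FALSE
  )
  out <- lapply(seq_len(J), function(j) {
    df <- base
    df$final_value <- I_all[, j]
    df$choice <- ifelse(df$final_value > 0, "up",
                        ifelse(df$final_value < 0, "down",
                               ifelse(coin, "up", "down")))
    attr(df, "seed") <- as.integer(seed)
    class(df) <- c("lg_trials", "data.frame")
    df
  })
  if (keep_counts) attr(out, "counts") <- counts
  out
}

#' Simulate a full experiment under one model variant
#'
#' For every cell of the task x strength grid, simulates
#' `trials_per_condition` independent trials: bank rates are read from
#' the population table, Bernoulli spike trains generated for the eight
#' bank neurons, differential signals integrated, and the sign rule
#' applied.  Reproducible for a fixed seed.
#'
#' @param table A [population_rate_table()].
#' @param grid Signed stimulus strengths (subset of the table grid),
#'   applied to both features.
#' @param config An [integrator_config()].
#' @param trials_per_condition Trials per (task, C_dir, C_dep) cell
#'   (default 1000).
#' @param seed Integer master seed.
#' @param keep_counts Keep per-trial 100-ms-bin spike counts of the
#'   eight bank neurons (needed for choice-probability analyses)?
#' @param tasks Tasks to simulate.
#' @return A data frame of class `lg_trials` with one row per trial:
#'   `task`, `c_dir`, `c_dep`, `trial`, `final_value`, `choice`.  When
#'   `keep_counts = TRUE` an array attribute `counts`
#'   (trial x neuron x bin) is attached.
#' @export
run_experiment <- function(table, grid, config, trials_per_condition = 1000,
                           seed = 1L, keep_counts = FALSE,
                           tasks = c("direction", "depth")) {
  stopifnot(inherits(config, "integrator_config"))
  res <- sim_experiment_core(table, grid, list(integration_weights(config)),
                             trials_per_condition, seed, keep_counts,
                             tasks, config$step)
  out <- res[[1]]
  if (keep_counts) attr(out, "counts") <- attr(res, "counts")
  attr(out, "config") <- config
  out
}

#' Simulate several model variants on shared spike trains
#'
#' Identical to [run_experiment()] but evaluates every configuration in
#' `configs` on the *same* simulated spike trains, which is the setting
#' in which the double-leaky and time-varying-gate models make exactly
#' the same choices.
#'
#' @inheritParams run_experiment
#' @param configs A list of [integrator_config()] objects.
#' @return A list of `lg_trials` data frames, one per configuration, in
#'   the same trial order.
#' @export
run_experiment_set <- function(table, grid, configs,
                               trials_per_condition = 1000, seed = 1L,
                               keep_counts = FALSE,
                               tasks = c("direction", "depth")) {
  stopifnot(length(configs) >= 1,
            all(vapply(configs, inherits, logical(1), "integrator_config")))
  wts <- lapply(configs, integration_weights)
  res <- sim_experiment_core(table, grid, wts, trials_per_condition, seed,
                             keep_counts, tasks, configs[[1]]$step)
  for (j in seq_along(res)) attr(res[[j]], "config") <- configs[[j]]
  res
}

#' Simulate an experiment with late task commitment
#'
#' Before the commitment time `t_c` the model has not yet adopted its
#' task-specific parameters: with `initial_regime = "open"` both
#' streams are integrated unweighted and leak-free, with `"closed"`
#' neither stream is integrated.  From `t_c` onward the variant's own
#' regime applies: the gated model applies its weight, the leaky models
#' apply their leak (so irrelevant evidence accumulated before `t_c`
#' decays by `exp(-k (tau1 - t_c))` under the double-leaky model), and
#' the time-varying gate re-anchors its opening schedule to `t_c`.  The
#' decision is still taken at `tau1`.
#'
#' @inheritParams run_experiment
#' @param t_c Commitment time in ms; values below `tau0` are clamped to
#'   `tau0` (pre-committed), values above `tau1` to `tau1`.
#' @param initial_regime "open" or "closed".
#' @return A data frame of class `lg_trials` with attributes `t_c` and
#'   `regime`.
#' @export
run_late_commitment <- function(table, grid, config, t_c,
                                initial_regime = c("open", "closed"),
                                trials_per_condition = 1000, seed = 1L,
                                tasks = c("direction", "depth")) {
  initial_regime <- match.arg(initial_regime)
  wt <- integration_weights(config, t_c = t_c, regime = initial_regime)
  res <- sim_experiment_core(table, grid, list(wt), trials_per_condition,
                             seed, FALSE, tasks, config$step)
  out <- res[[1]]
  attr(out, "config") <- config
  attr(out, "t_c") <- min(max(t_c, config$tau0), config$tau1)
  attr(out, "regime") <- initial_regime
  out
}

#' Sweep the task-commitment time for several models and regimes
#'
#' Runs [run_late_commitment()] across a grid of commitment times and
#' summarizes each run behaviorally: switch ratio, per-task 75%
#' thresholds and overall percent correct.
#'
#' @inheritParams run_experiment
#' @param configs Named list of [integrator_config()] objects.
#' @param t_c_values Commitment times in ms (default 0 to 600 in steps
#'   of 50, clamped into the integration window).
#' @param regimes Initial regimes to sweep.
#' @return A data frame with one row per (model, regime, t_c):
#'   `model`, `regime`, `t_c`, `sr`, `threshold_direction`,
#'   `threshold_depth`, `pct_correct`.
#' @export
commitment_sweep <- function(table, grid, configs,
                             t_c_values = seq(0, 600, by = 50),
                             regimes = c("open", "closed"),
                             trials_per_condition = 1000, seed = 1L) {
  if (is.null(names(configs))) {
    names(configs) <- vapply(configs, function(c) c$variant, character(1))
  }
  rows <- list()
  seeds <- derive_seeds(seed, length(configs) * length(regimes) *
                          length(t_c_values))
  si <- 0L
  for (m in names(configs)) {
    for (rg in regimes) {
      for (tc in t_c_values) {
        si <- si + 1L
        tr <- run_late_commitment(table, grid, configs[[m]], tc, rg,
                                  trials_per_condition, seeds[si])
        sr <- tryCatch(sr_from_trials(tr)$value, error = function(e) NA_real_)
        thr_dir <- tryCatch(
          threshold_75(tr[tr$task == "direction", ])$threshold,
          error = function(e) NA_real_)
        thr_dep <- tryCatch(
          threshold_75(tr[tr$task == "depth", ])$threshold,
          error = function(e) NA_real_)
        rows[[length(rows) + 1L]] <- data.frame(
          model = m, regime = rg,
          t_c = min(max(tc, configs[[m]]$tau0), configs[[m]]$tau1),
          sr = sr, threshold_direction = thr_dir,
          threshold_depth = thr_dep,
          pct_correct = percent_correct(tr),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}
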