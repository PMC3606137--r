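# Configuration, serialization and the command front ends tying the
# pipeline together.  Configs round-trip through JSON; every command
# writes a manifest naming the package version, the master seed and a
# fingerprint of the resolved configuration, so re-running a command
# with the same inputs is reproducible.

#' Build a run configuration
#'
#' Collects every knob of the simulation pipeline in one list.  Defaults
#' are the package's stated world: a 117-neuron population, the
#' symmetric 9-level strength grid, 1000 trials per condition and 10000
#' bootstrap replicates.
#'
#' @param n_neurons Synthetic population size.
#' @param tuning_balanced Use the balanced (equal-gain) tuning
#'   configuration?
#' @param grid Signed strength levels for both features.
#' @param table_trials_per_condition Repeats per (neuron, condition,
#'   task) when building the rate table.
#' @param variant,k,w Integrator variant and parameters (see
#'   [integrator_config()]).
#' @param trials_per_condition Simulated trials per (task, condition)
#'   cell.
#' @param t_c_values,regimes Commitment-time sweep settings.
#' @param n_boot Bootstrap replicates for choice-probability intervals.
#' @param seed Master seed; all stage seeds derive from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_neurons = 117, tuning_balanced = FALSE,
                       grid = stimulus_grid(),
                       table_trials_per_condition = 20,
                       variant = "gated", k = 0, w = 0.3,
                       trials_per_condition = 1000,
                       t_c_values = seq(0, 600, by = 50),
                       regimes = c("open", "closed"),
                       n_boot = 10000, seed = 1L) {
  cfg <- list(
    n_neurons = n_neurons, tuning_balanced = tuning_balanced,
    grid = grid,
    table_trials_per_condition = table_trials_per_condition,
    variant = variant, k = k, w = w,
    trials_per_condition = trials_per_condition,
    t_c_values = t_c_values, regimes = regimes,
    n_boot = n_boot, seed = as.integer(seed)
  )
  # validate the model part early
  invisible(config_to_integrator(cfg))
  class(cfg) <- "run_config"
  cfg
}

config_to_integrator <- function(cfg) {
  integrator_config(cfg$variant, k = cfg$k, w = cfg$w)
}

#' Write / read a run configuration as JSON
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `read_run_config` returns the `run_config`;
#'   `write_run_config` returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

config_json <- function(config) {
  jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
}

#' Serialize trial records to CSV
#'
#' Columns: `task`, `c_dir`, `c_dep`, `trial`, `final_value`, `choice`
#' (strengths are unitless signed fractions; `final_value` is the
#' integrated evidence in spike units).
#'
#' @param trials An `lg_trials` data frame.
#' @param path File path.
#' @return `path`, invisibly (`read_trials_csv` returns the data
#'   frame).
#' @export
write_trials_csv <- function(trials, path) {
  write.csv(as.data.frame(trials)[c("task", "c_dir", "c_dep", "trial",
                                    "final_value", "choice")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("lg_trials", "data.frame")
  df
}

#' Serialize a population rate table to CSV
#'
#' Long format with explicit units in the column names:
#' `tau_ms`, `c_dir`, `c_dep`, `task`, `rate_spikes_per_ms`.
#'
#' @param table A [population_rate_table()].
#' @param path File path.
#' @return `path` invisibly; `read_rate_table_csv` rebuilds the
#'   `population_rate_table` object.
#' @export
write_rate_table_csv <- function(table, path) {
  grid_d <- table$c_dir_levels
  grid_p <- table$c_dep_levels
  rows <- expand.grid(tau_ms = table$tau, c_dir = grid_d, c_dep = grid_p,
                      task = table$tasks, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  rows$rate_spikes_per_ms <- as.vector(table$rates)
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rate_table_csv
#' @export
read_rate_table_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  tau <- sort(unique(df$tau_ms))
  grid_d <- sort(unique(df$c_dir))
  grid_p <- sort(unique(df$c_dep))
  tasks <- unique(df$task)
  rates <- array(
    0, dim = c(length(tau), length(grid_d), length(grid_p),
               length(tasks)),
    dimnames = list(NULL, signif(grid_d, 10), signif(grid_p, 10), tasks)
  )
  # rebuild in the expand.grid order used by the writer
  ord <- order(match(df$task, tasks), match(df$c_dep, grid_p),
               match(df$c_dir, grid_d), match(df$tau_ms, tau))
  rates[] <- df$rate_spikes_per_ms[ord]
  structure(
    list(rates = rates, tau = tau, c_dir_levels = grid_d,
         c_dep_levels = grid_p, tasks = tasks,
         n_neurons = NA_integer_, trials_per_condition = NA_integer_,
         seed = NA_integer_),
    class = "population_rate_table"
  )
}

#' Serialize per-trial bank spikes to CSV (one row per spike)
#'
#' Columns: `trial_id`, `neuron_id`, `task`, `c_dir`, `c_dep`, `choice`,
#' `spike_time_ms`.  A companion trials manifest (see
#' [write_trials_csv()]) carries one row per trial.
#'
#' @param spikes Data frame in the per-spike layout above.
#' @param path File path.
#' @return `path` invisibly; the reader returns the data frame.
#' @export
write_spikes_csv <- function(spikes, path) {
  write.csv(spikes[c("trial_id", "neuron_id", "task", "c_dir", "c_dep",
                     "choice", "spike_time_ms")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes_csv
#' @export
read_spikes_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

# Simulate per-spike rows for the eight bank neurons (for the spike CSV
# and CP-from-file path).  Regenerates the trains with the same seeds as
# sim_experiment_core so the spike files match the trial records.
bank_spike_rows <- function(table, grid, config, trials_per_condition,
                            seed, tasks = c("direction", "depth")) {
  grid <- sort(unique(grid))
  times <- table$tau
  nt <- as.integer(trials_per_condition)
  cells <- expand.grid(task = tasks, c_dir = grid, c_dep = grid,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  seeds <- derive_seeds(seed, nrow(cells))
  trials <- run_experiment(table, grid, config, trials_per_condition,
                           seed, tasks = tasks)
  rows <- vector("list", nrow(cells) * 8L)
  ri <- 0L
  for (ci in seq_len(nrow(cells))) {
    set.seed(seeds[ci])
    R8 <- bank_rates(table, cells$c_dir[ci], cells$c_dep[ci],
                     cells$task[ci])
    p <- pmin(R8 * config$step, 1)
    trial_ids <- ((ci - 1L) * nt + 1L):(ci * nt)
    for (n in 1:8) {
      S <- matrix(runif(nt * length(times)) < rep(p[, n], each = nt),
                  nt, length(times))
      hit <- which(S, arr.ind = TRUE)
      ri <- ri + 1L
      if (nrow(hit) == 0L) next
      rows[[ri]] <- data.frame(
        trial_id = trial_ids[hit[, 1]],
        neuron_id = n,
        task = cells$task[ci],
        c_dir = cells$c_dir[ci],
        c_dep = cells$c_dep[ci],
        choice = trials$choice[trial_ids[hit[, 1]]],
        spike_time_ms = times[hit[, 2]],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$trial_id, out$neuron_id, out$spike_time_ms), ]
  rownames(out) <- NULL
  list(spikes = out, trials = trials)
}

write_manifest <- function(path, config, extra = list()) {
  manifest <- c(list(
    package = "leakygate",
    version = as.character(utils::packageVersion("leakygate")),
    seed = config$seed,
    config_fingerprint = config_fingerprint(config_json(config))
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Simulate and write trial, spike and rate-table CSV files
#'
#' Runs the full pipeline for `config`: builds the synthetic population
#' and its rate table, simulates the configured model over the grid, and
#' writes `trials.csv`, `spikes.csv`, `rate_table.csv`, the resolved
#' `config.json` and a `manifest.json` (package version, seed, config
#' fingerprint, model parameters) into `outdir`.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a named list of the written file paths.
#' @export
cmd_simulate <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 3)
  pop <- mt_population(config$n_neurons, seeds[1],
                       mt_tuning_defaults(config$tuning_balanced))
  table <- population_rate_table(pop, config$grid,
                                 config$table_trials_per_condition,
                                 seeds[2])
  icfg <- config_to_integrator(config)
  sim <- bank_spike_rows(table, config$grid, icfg,
                         config$trials_per_condition, seeds[3])
  paths <- list(
    trials = file.path(outdir, "trials.csv"),
    spikes = file.path(outdir, "spikes.csv"),
    rate_table = file.path(outdir, "rate_table.csv"),
    config = file.path(outdir, "config.json"),
    manifest = file.path(outdir, "manifest.json")
  )
  write_trials_csv(sim$trials, paths$trials)
  write_spikes_csv(sim$spikes, paths$spikes)
  write_rate_table_csv(table, paths$rate_table)
  write_run_config(config, paths$config)
  write_manifest(paths$manifest, config,
                 list(variant = icfg$variant, k = icfg$k,
                      w = if (is.na(icfg$w)) NULL else icfg$w,
                      n_trials = nrow(sim$trials)))
  invisible(paths)
}

#' Fit the behavioral models to a trials CSV
#'
#' Reads trial records, fits the eight-parameter logistic model, the
#' nine-parameter wrong-task mixture, the switch ratio and the per-task
#' 75% thresholds, and writes them as JSON.
#'
#' @param trials_csv Path to a trials CSV ([write_trials_csv()] layout).
#' @param out_json Output JSON path.
#' @param seed Seed for the mixture restarts.
#' @return Invisibly, the result list written to `out_json`.
#' @export
cmd_fit <- function(trials_csv, out_json, seed = 1L) {
  trials <- read_trials_csv(trials_csv)
  both <- fit_logistic_both(trials)
  mix <- fit_mixture(trials, seed = seed)
  sr <- switch_ratio(both$direction, both$depth)
  thr <- lapply(c(direction = "direction", depth = "depth"), function(tk) {
    tryCatch({
      t <- threshold_75(trials[trials$task == tk, ])
      list(threshold = t$threshold, alpha = t$alpha, beta = t$beta,
           above_max = t$above_max, below_min = t$below_min)
    }, error = function(e) list(threshold = NULL,
                                reason = conditionMessage(e)))
  })
  res <- list(
    logistic_8param = list(
      direction = as.list(both$direction$coef),
      depth = as.list(both$depth$coef),
      logLik = both$logLik, aic = both$aic,
      converged = both$direction$converged && both$depth$converged
    ),
    mixture_9param = list(
      direction = as.list(mix$coef_direction),
      depth = as.list(mix$coef_depth),
      p_err = mix$p_err, logLik = mix$logLik, aic = mix$aic,
      converged = mix$converged
    ),
    switch_ratio = list(value = sr$value,
                        dir_component = sr$dir_component,
                        dep_component = sr$dep_component),
    thresholds = thr,
    seed = as.integer(seed)
  )
  jsonlite::write_json(res, out_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(res)
}

#' Choice-probability time course from spike and trial CSVs
#'
#' Reads per-spike rows and trial records, bins spikes into the eight
#' 100-ms windows, and runs [cp_timecourse()]; results are written as
#' CSV (`bin_start_ms`, `group`, `task_relation`, `cp`, `ci_low`,
#' `ci_high`, `n_pref`, `n_null`).
#'
#' @param spikes_csv,trials_csv Input CSV paths ([write_spikes_csv()] /
#'   [write_trials_csv()] layouts).
#' @param out_csv Output CSV path.
#' @param n_boot Bootstrap replicates.
#' @param seed Bootstrap seed.
#' @return Invisibly, the [cp_timecourse()] data frame.
#' @export
cmd_cp <- function(spikes_csv, trials_csv, out_csv, n_boot = 10000,
                   seed = 1L) {
  spikes <- read_spikes_csv(spikes_csv)
  trials <- read_trials_csv(trials_csv)
  bins <- seq(-100, 600, by = 100)
  counts <- array(
    0L, dim = c(nrow(trials), 8L, length(bins)),
    dimnames = list(NULL, paste0("n", 1:8), bins)
  )
  bi <- findInterval(spikes$spike_time_ms, c(bins, max(bins) + 100))
  ok <- bi >= 1 & bi <= length(bins)
  agg <- aggregate(
    list(n = rep(1L, sum(ok))),
    by = list(trial = spikes$trial_id[ok], neuron = spikes$neuron_id[ok],
              bin = bi[ok]),
    FUN = sum
  )
  counts[cbind(agg$trial, agg$neuron, agg$bin)] <- agg$n
  attr(trials, "counts") <- counts
  cp <- cp_timecourse(trials, n_boot = n_boot, seed = seed)
  out <- data.frame(
    bin_start_ms = cp$bin_start, group = cp$group,
    task_relation = cp$task_relation, cp = cp$cp,
    ci_low = cp$ci_low, ci_high = cp$ci_high,
    n_pref = cp$n_pref, n_null = cp$n_null
  )
  write.csv(out, out_csv, row.names = FALSE)
  invisible(cp)
}

#' Commitment-time sweep command
#'
#' Builds the configured synthetic world, sweeps the task-commitment
#' time for the three model variants of interest (gated with the
#' configured `w`, time-varying gate and double-leaky with the
#' configured `k`) in both initial regimes, and writes one row per
#' (model, regime, t_c) with SR, thresholds and percent correct.
#'
#' @param config A [run_config()]; `w` and `k` set the gated and
#'   gate/leak parameters.
#' @param out_csv Output CSV path.
#' @return Invisibly, the sweep data frame.
#' @export
cmd_commitment <- function(config, out_csv) {
  stopifnot(inherits(config, "run_config"))
  seeds <- derive_seeds(config$seed, 3)
  pop <- mt_population(config$n_neurons, seeds[1],
                       mt_tuning_defaults(config$tuning_balanced))
  table <- population_rate_table(pop, config$grid,
                                 config$table_trials_per_condition,
                                 seeds[2])
  k <- if (config$k > 0) config$k else 1 / 110
  configs <- list(
    gated = integrator_config("gated", w = config$w),
    time_varying_gate = integrator_config("time_varying_gate", k = k),
    double_leaky = integrator_config("double_leaky", k = k)
  )
  sweep <- commitment_sweep(table, config$grid, configs,
                            config$t_c_values, config$regimes,
                            config$trials_per_condition, seeds[3])
  write.csv(sweep, out_csv, row.names = FALSE)
  invisible(sweep)
}
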