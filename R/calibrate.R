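# Calibration of the irrelevant-stream parameters against a behavioral
# switch-ratio target.  Both searches evaluate every candidate on shared
# spike trains (the gated final value is linear in w, and the gate/leak
# weights enter the decision linearly), then re-simulate the winner with
# fresh seeds so the reported SR is out-of-sample.

sr_curve <- function(table, grid, configs, trials_per_condition, seed) {
  runs <- run_experiment_set(table, grid, configs, trials_per_condition,
                             seed)
  vapply(runs, function(tr) {
    tryCatch(sr_from_trials(tr)$value, error = function(e) NA_real_)
  }, numeric(1))
}

#' Calibrate the gated-integrator weight against a switch-ratio target
#'
#' Sweeps the constant gate weight from 0 to 1 in steps of `step`
#' (default 0.02), simulating all weights on shared spike trains, picks
#' the weight whose simulated SR is closest to `target_sr`, and
#' re-simulates at that weight with a fresh seed.
#'
#' @param table A [population_rate_table()].
#' @param grid Stimulus strengths for the simulated experiments.
#' @param target_sr Behavioral switch-ratio target in (0, 1) (0.70 is
#'   the canonical behavioral average).
#' @param step Weight grid step (default 0.02).
#' @param trials_per_condition Trials per cell during the sweep and the
#'   confirmation run.
#' @param seed Master seed.
#' @return A list of class `calibration`: `parameter` ("w"), `value`
#'   (the selected weight), `sr` (re-simulated SR at the selection),
#'   `target`, `curve` (data frame of the full SR-vs-parameter sweep)
#'   and `target_achievable`.
#' @export
calibrate_weight <- function(table, grid, target_sr = 0.70, step = 0.02,
                             trials_per_condition = 300, seed = 1L) {
  if (target_sr <= 0 || target_sr >= 1) {
    stop("`target_sr` must lie in (0, 1)", call. = FALSE)
  }
  ws <- seq(0, 1, by = step)
  configs <- lapply(ws, function(w) integrator_config("gated", w = w))
  seeds <- derive_seeds(seed, 2)
  srs <- sr_curve(table, grid, configs, trials_per_condition, seeds[1])
  best <- which.min(abs(srs - target_sr))
  achievable <- target_sr >= min(srs, na.rm = TRUE) &&
    target_sr <= max(srs, na.rm = TRUE)
  if (!achievable) {
    warning(sprintf(
      "target SR %.2f outside achievable range [%.2f, %.2f]",
      target_sr, min(srs, na.rm = TRUE), max(srs, na.rm = TRUE)),
      call. = FALSE)
  }
  confirm <- run_experiment(table, grid, configs[[best]],
                            trials_per_condition, seeds[2])
  structure(
    list(parameter = "w", value = ws[best],
         sr = sr_from_trials(confirm)$value, target = target_sr,
         curve = data.frame(w = ws, sr = srs),
         target_achievable = achievable),
    class = "calibration"
  )
}

#' Calibrate the time-varying-gate time constant
#'
#' Line search of the gate time constant (ms) over `tau_values`: all
#' candidates are simulated on shared spike trains, the candidate with
#' SR closest to `target_sr` is selected and re-simulated with a fresh
#' seed.  The gate rate is `k = 1/tau`.
#'
#' @inheritParams calibrate_weight
#' @param tau_values Candidate time constants in ms (default 10-500).
#' @return A list of class `calibration` (see [calibrate_weight()]);
#'   `parameter` is "time_constant" and `curve` has columns
#'   `time_constant`, `sr`.
#' @export
calibrate_time_constant <- function(table, grid, target_sr = 0.70,
                                    tau_values = seq(10, 500, by = 10),
                                    trials_per_condition = 300,
                                    seed = 1L) {
  if (target_sr <= 0 || target_sr >= 1) {
    stop("`target_sr` must lie in (0, 1)", call. = FALSE)
  }
  configs <- lapply(tau_values, function(tc) {
    integrator_config("time_varying_gate", k = 1 / tc)
  })
  seeds <- derive_seeds(seed, 2)
  srs <- sr_curve(table, grid, configs, trials_per_condition, seeds[1])
  best <- which.min(abs(srs - target_sr))
  achievable <- target_sr >= min(srs, na.rm = TRUE) &&
    target_sr <= max(srs, na.rm = TRUE)
  if (!achievable) {
    warning(sprintf(
      "target SR %.2f outside achievable range [%.2f, %.2f]",
      target_sr, min(srs, na.rm = TRUE), max(srs, na.rm = TRUE)),
      call. = FALSE)
  }
  confirm <- run_experiment(table, grid, configs[[best]],
                            trials_per_condition, seeds[2])
  structure(
    list(parameter = "time_constant", value = tau_values[best],
         sr = sr_from_trials(confirm)$value, target = target_sr,
         curve = data.frame(time_constant = tau_values, sr = srs),
         target_achievable = achievable),
    class = "calibration"
  )
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf(
    "calibration: %s = %g (re-simulated SR %.3f, target %.2f)%s\n",
    x$parameter, x$value, x$sr, x$target,
    if (!x$target_achievable) " [target outside achievable range]" else ""))
  invisible(x)
}
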