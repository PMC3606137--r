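# The general two-accumulator model and its four parametrizations.  Per
# 1-ms step the accumulators follow
#   I_rel <- I_rel * exp(-k_relevant * dt) + i_rel(tau) * dt
#   I_irr <- I_irr * exp(-k_irrelevant * dt) + w(tau) * i_irr(tau) * dt
# over the integration window (tau0, tau1]; the decision is the sign of
# I_rel + I_irr at tau1.  The exact per-step decay factor exp(-k dt)
# (rather than forward Euler) makes the double-leaky model and the
# time-varying-gate model agree choice-for-choice on shared spike trains:
# both weight the irrelevant input at time tau by exp(-k (tau1 - tau)).

#' Configure an integrator model variant
#'
#' The four variants constrain the general model as follows:
#' \describe{
#'   \item{gated}{`k_relevant = k_irrelevant = 0`, constant weight `w`.}
#'   \item{time_varying_gate}{`k_relevant = k_irrelevant = 0`,
#'     `w(tau) = exp(k (tau - tau1))` (gate opens exponentially toward 1
#'     at decision time).}
#'   \item{single_leaky}{`k_relevant = k_irrelevant = k`, constant `w`.}
#'   \item{double_leaky}{`k_relevant = 0`, `k_irrelevant = k`, `w = 1`.}
#' }
#'
#' @param variant Model variant name.
#' @param k Leak rate / gate rate in 1/ms (e.g. a 110-ms time constant is
#'   `k = 1/110`).  Ignored by "gated".
#' @param w Constant weight on the irrelevant stream in \[0, 1\]
#'   ("gated" and "single_leaky" only).
#' @param tau0 Integration start, ms after stimulus onset (default 100,
#'   when stimulus-driven responses arise).
#' @param tau1 Integration end, ms (default 600, 100 ms after stimulus
#'   offset; `tau1 - tau0 = 500` ms of integration).
#' @param step Integration step in ms (1).
#' @return A list of class `integrator_config`.
#' @export
integrator_config <- function(variant = c("gated", "time_varying_gate",
                                          "single_leaky", "double_leaky"),
                              k = 0, w = 1, tau0 = 100, tau1 = 600,
                              step = 1) {
  variant <- match.arg(variant)
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 0) {
    stop("`k` must be a non-negative rate in 1/ms", call. = FALSE)
  }
  if (!is.numeric(w) || length(w) != 1L || w < 0 || w > 1) {
    stop("`w` must lie in [0, 1]", call. = FALSE)
  }
  if (tau1 <= tau0) stop("`tau1` must exceed `tau0`", call. = FALSE)
  cfg <- switch(variant,
    gated = list(k_relevant = 0, k_irrelevant = 0, w = w, k = 0),
    time_varying_gate = list(k_relevant = 0, k_irrelevant = 0, w = NA_real_,
                             k = k),
    single_leaky = list(k_relevant = k, k_irrelevant = k, w = w, k = k),
    double_leaky = list(k_relevant = 0, k_irrelevant = k, w = 1, k = k)
  )
  structure(
    c(list(variant = variant), cfg,
      list(tau0 = tau0, tau1 = tau1, step = step)),
    class = "integrator_config"
  )
}

#' @export
print.integrator_config <- function(x, ...) {
  cat(sprintf(
    "integrator_config: %s (k_rel=%g, k_irr=%g, w=%s, window %g-%g ms)\n",
    x$variant, x$k_relevant, x$k_irrelevant,
    if (is.na(x$w)) sprintf("exp(%g*(tau-tau1))", x$k) else format(x$w),
    x$tau0, x$tau1))
  invisible(x)
}

# Weight w(tau) on the irrelevant stream, evaluated at bin-end times.
gate_weight <- function(config, tau_end) {
  if (config$variant == "time_varying_gate") {
    exp(config$k * (tau_end - config$tau1))
  } else {
    rep(config$w, length(tau_end))
  }
}

# Effective decision weights on each 1-ms contribution: the recursion
# above unrolls to I(tau1) = sum_tau a(tau) i(tau) dt with
# a_rel = exp(-k_rel (tau1 - tau)) and a_irr = exp(-k_irr (tau1 - tau)) w(tau),
# tau running over bin-end times tau0+step, ..., tau1.  `t_c` and
# `regime` implement late task commitment (see [run_late_commitment()]).
integration_weights <- function(config, t_c = NULL, regime = NULL) {
  dt <- config$step
  tau <- seq(config$tau0 + dt, config$tau1, by = dt)
  if (is.null(t_c)) {
    a_rel <- exp(-config$k_relevant * (config$tau1 - tau)) * dt
    a_irr <- exp(-config$k_irrelevant * (config$tau1 - tau)) *
      gate_weight(config, tau) * dt
    return(list(tau = tau, a_rel = a_rel, a_irr = a_irr))
  }
  t_c <- min(max(t_c, config$tau0), config$tau1)
  pre <- tau <= t_c
  if (regime == "open") {
    # both streams integrated unweighted and leak-free before t_c; the
    # irrelevant accumulator's pre-commitment content then decays (leaky
    # variants) or simply persists (gate variants)
    a_rel <- exp(-config$k_relevant * (config$tau1 - pmax(tau, t_c))) * dt
    a_irr <- exp(-config$k_irrelevant * (config$tau1 - pmax(tau, t_c))) * dt
    w_post <- commitment_gate(config, tau, t_c)
    a_irr[!pre] <- a_irr[!pre] * w_post[!pre]
  } else if (regime == "closed") {
    a_rel <- ifelse(pre, 0, exp(-config$k_relevant * (config$tau1 - tau))) * dt
    a_irr <- ifelse(pre, 0,
                    exp(-config$k_irrelevant * (config$tau1 - tau)) *
                      commitment_gate(config, tau, t_c)) * dt
  } else {
    stop("`initial_regime` must be 'open' or 'closed'", call. = FALSE)
  }
  list(tau = tau, a_rel = a_rel, a_irr = a_irr)
}

# Post-commitment gate schedule.  The time-varying gate re-anchors to the
# commitment time (its schedule spans one full integration window from
# t_c), since a schedule fixed to tau1 would leave the gate nearly open
# for late commitments.
commitment_gate <- function(config, tau, t_c) {
  if (config$variant == "time_varying_gate") {
    exp(config$k * (tau - (t_c + (config$tau1 - config$tau0))))
  } else {
    rep(config$w, length(tau))
  }
}

#' Integrate the differential signals of one trial
#'
#' Runs the per-1-ms-step recursion of the general model on one trial's
#' differential signals and applies the sign decision rule: positive
#' integrated value gives an upward choice, negative a downward choice,
#' an exact zero is resolved by a fair coin.
#'
#' @param signals A [differential_signals()] object covering the trial
#'   grid.
#' @param task "direction" (relevant stream `i_dir`) or "depth"
#'   (relevant stream `i_dep`).
#' @param config An [integrator_config()].
#' @param seed Optional seed for the tie-breaking coin.
#' @param times Time grid (bin starts) of the signals.
#' @return A one-row data frame (class `trial_record`): `task`, `c_dir`,
#'   `c_dep` (NA here), `trial`, `final_value`, `choice`.
#' @export
integrate_trial <- function(signals, task = c("direction", "depth"),
                            config, seed = NULL, times = trial_times()) {
  task <- match.arg(task)
  stopifnot(inherits(config, "integrator_config"))
  i_rel <- if (task == "direction") signals$i_dir else signals$i_dep
  i_irr <- if (task == "direction") signals$i_dep else signals$i_dir
  if (length(i_rel) != length(times)) {
    stop("signals do not cover the trial grid", call. = FALSE)
  }
  dt <- config$step
  tau_end <- seq(config$tau0 + dt, config$tau1, by = dt)
  # bin with start time tau contributes at its end time tau + dt
  idx <- match(tau_end - dt, times)
  if (any(is.na(idx))) {
    stop("signals do not cover the integration window", call. = FALSE)
  }
  w <- gate_weight(config, tau_end)
  d_rel <- exp(-config$k_relevant * dt)
  d_irr <- exp(-config$k_irrelevant * dt)
  I_rel <- 0
  I_irr <- 0
  for (j in seq_along(idx)) {
    I_rel <- I_rel * d_rel + i_rel[idx[j]] * dt
    I_irr <- I_irr * d_irr + w[j] * i_irr[idx[j]] * dt
  }
  I <- I_rel + I_irr
  if (!is.null(seed)) set.seed(as.integer(seed))
  choice <- if (I > 0) "up" else if (I < 0) "down" else {
    if (runif(1) < 0.5) "up" else "down"
  }
  structure(
    data.frame(task = task, c_dir = NA_real_, c_dep = NA_real_,
               trial = 1L, final_value = I, choice = choice,
               stringsAsFactors = FALSE),
    class = c("trial_record", "data.frame")
  )
}
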