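# Shared fixtures, built once per test run and cached.

.world <- new.env(parent = emptyenv())

# Default synthetic population (117 neurons) and its rate table on the
# default 9-level grid; used by the acceptance suite and the heavier
# property tests.
default_pop <- function() {
  if (is.null(.world$pop)) .world$pop <- mt_population(117, seed = 1)
  .world$pop
}

default_table <- function() {
  if (is.null(.world$table)) {
    .world$table <- population_rate_table(default_pop(), stimulus_grid(),
                                          trials_per_condition = 20,
                                          seed = 2)
  }
  .world$table
}

# 5-level grid used for the switch-ratio endpoint and calibration runs.
grid5 <- function() stimulus_grid(c(0.125, 0.5))

# Hand-crafted deterministic rate table: rate(tau; c, d) = base + a*c +
# b*d (spikes/ms, clipped at 0), constant over time and identical for
# both tasks.  Lets readout/integrator tests verify sign mappings and
# arithmetic exactly.
toy_table <- function(base = 0.02, a = 0.02, b = 0.01,
                      grid = c(-0.5, -0.25, 0, 0.25, 0.5)) {
  tau <- trial_times()
  rates <- array(
    0, dim = c(length(tau), length(grid), length(grid), 2),
    dimnames = list(NULL, signif(grid, 10), signif(grid, 10),
                    c("direction", "depth"))
  )
  for (i in seq_along(grid)) {
    for (j in seq_along(grid)) {
      rates[, i, j, ] <- max(base + a * grid[i] + b * grid[j], 0)
    }
  }
  structure(
    list(rates = rates, tau = tau, c_dir_levels = grid,
         c_dep_levels = grid, tasks = c("direction", "depth"),
         n_neurons = 1L, trials_per_condition = NA_integer_,
         seed = NA_integer_),
    class = "population_rate_table"
  )
}

# Brute-force ROC area by exhaustive pair enumeration (oracle for
# roc_area).
roc_area_bruteforce <- function(pref, null) {
  wins <- 0
  for (x in pref) for (y in null) {
    wins <- wins + (x > y) + 0.5 * (x == y)
  }
  wins / (length(pref) * length(null))
}

# Simulate choices directly from the logistic / mixture model (oracle
# world for the psychometric recovery tests).
simulate_choice_data <- function(beta_dir, beta_dep, p_err = 0,
                                 grid = stimulus_grid(c(0.125, 0.25, 0.5)),
                                 n_per_cond = 200, seed = 1) {
  set.seed(seed)
  cells <- expand.grid(task = c("direction", "depth"), c_dir = grid,
                       c_dep = grid, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    ce <- cells[i, ]
    own <- if (ce$task == "direction") beta_dir else beta_dep
    oth <- if (ce$task == "direction") beta_dep else beta_dir
    lp <- function(b) b[1] + b[2] * ce$c_dir + b[3] * ce$c_dep +
      b[4] * ce$c_dir * ce$c_dep
    p <- (1 - p_err) * plogis(lp(own)) + p_err * plogis(lp(oth))
    up <- rbinom(1, n_per_cond, p)
    data.frame(task = ce$task, c_dir = ce$c_dir, c_dep = ce$c_dep,
               trial = seq_len(n_per_cond),
               final_value = NA_real_,
               choice = c(rep("up", up), rep("down", n_per_cond - up)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("lg_trials", "data.frame")
  out
}
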