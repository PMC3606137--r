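# Synthetic MT population: a parametric stand-in for a recorded population
# of direction- and depth-tuned neurons.  Each neuron has a baseline rate,
# linear tuning gains along the (signed, preference-relative) coherence and
# correlation axes, a response latency, and an optional multiplicative
# onset transient with exponential decay.  Spiking is Bernoulli per 1-ms
# bin (the discrete Poisson front end); rates are estimated back from
# spikes by a truncated-Gaussian kernel density estimate.

#' Default tuning configuration for the synthetic MT population
#'
#' Parameter distributions from which [mt_population()] draws neuron
#' properties.  Units: rates and gains in spikes/s (per unit signed
#' strength for the gains), latency and time constants in ms.  The default
#' direction gain (mean 40 spikes/s per unit coherence) deliberately
#' exceeds the depth gain (mean 20 spikes/s per unit correlation): MT
#' populations are on average more sensitive to motion direction than to
#' binocular depth, which is what drives the asymmetry between the two
#' simulated tasks.  `balanced = TRUE` equalizes the two gain
#' distributions (mean 30 spikes/s, tighter spread), emulating a selected
#' sub-population with matched direction/depth sensitivity.
#'
#' @param balanced Logical; use the balanced (equal-gain) configuration.
#' @return A list of distribution parameters understood by
#'   [mt_population()].
#' @export
mt_tuning_defaults <- function(balanced = FALSE) {
  if (balanced) {
    list(
      baseline_mean = 20, baseline_shape = 4,
      dir_gain_mean = 30, dir_gain_sdlog = 0.25,
      depth_gain_mean = 30, depth_gain_sdlog = 0.25,
      latency_mean = 100, latency_sd = 8, latency_range = c(60, 160),
      transient_amp_range = c(0.3, 0.7),
      transient_tau_range = c(50, 150)
    )
  } else {
    list(
      baseline_mean = 20, baseline_shape = 4,
      dir_gain_mean = 40, dir_gain_sdlog = 0.5,
      depth_gain_mean = 20, depth_gain_sdlog = 0.5,
      latency_mean = 100, latency_sd = 8, latency_range = c(60, 160),
      transient_amp_range = c(0.3, 0.7),
      transient_tau_range = c(50, 150)
    )
  }
}

#' Generate a synthetic MT population
#'
#' Draws `n_neurons` neuron specifications from the tuning configuration.
#' Preference quadrants (up/far, down/far, up/near, down/near) are
#' assigned round-robin so that all four types are present whenever
#' `n_neurons >= 4`.  Gains are gamma-distributed (strictly positive, so
#' every neuron's rate is monotone non-decreasing in both strengths).
#'
#' @param n_neurons Number of neurons (>= 1).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param tuning Tuning configuration, see [mt_tuning_defaults()].
#' @return A data frame of class `mt_population` with one row per neuron:
#'   `id`, `pref_dir` ("up"/"down"), `pref_depth` ("far"/"near"),
#'   `baseline_rate`, `dir_gain`, `depth_gain` (spikes/s), `latency` (ms),
#'   `transient_amp`, `transient_tau` (ms).
#' @examples
#' pop <- mt_population(8, seed = 1)
#' table(pop$pref_dir, pop$pref_depth)
#' @export
mt_population <- function(n_neurons, seed = 1L,
                          tuning = mt_tuning_defaults()) {
  if (!is.numeric(n_neurons) || length(n_neurons) != 1L ||
      !is.finite(n_neurons) || n_neurons < 1) {
    stop("`n_neurons` must be a positive count", call. = FALSE)
  }
  n_neurons <- as.integer(n_neurons)
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  quadrants <- data.frame(
    pref_dir = c("up", "down", "up", "down"),
    pref_depth = c("far", "far", "near", "near"),
    stringsAsFactors = FALSE
  )
  qi <- ((seq_len(n_neurons) - 1L) %% 4L) + 1L

  # baseline: gamma (positive, mildly skewed); gains: lognormal with the
  # requested mean, giving the broad scatter of direction-vs-depth
  # tuning strength seen in MT (some neurons are depth-dominant even
  # though the population favors direction)
  gb <- list(shape = tuning$baseline_shape,
             scale = tuning$baseline_mean / tuning$baseline_shape)
  lognorm <- function(n, mean, sdlog) {
    exp(rnorm(n, log(mean) - sdlog^2 / 2, sdlog))
  }

  lat <- rnorm(n_neurons, tuning$latency_mean, tuning$latency_sd)
  lat <- pmin(pmax(lat, tuning$latency_range[1]), tuning$latency_range[2])

  pop <- data.frame(
    id = seq_len(n_neurons),
    pref_dir = quadrants$pref_dir[qi],
    pref_depth = quadrants$pref_depth[qi],
    baseline_rate = rgamma(n_neurons, shape = gb$shape, scale = gb$scale),
    dir_gain = lognorm(n_neurons, tuning$dir_gain_mean,
                       tuning$dir_gain_sdlog),
    depth_gain = lognorm(n_neurons, tuning$depth_gain_mean,
                         tuning$depth_gain_sdlog),
    latency = round(lat),
    transient_amp = runif(n_neurons, tuning$transient_amp_range[1],
                          tuning$transient_amp_range[2]),
    transient_tau = runif(n_neurons, tuning$transient_tau_range[1],
                          tuning$transient_tau_range[2]),
    stringsAsFactors = FALSE
  )
  attr(pop, "seed") <- as.integer(seed)
  attr(pop, "tuning") <- tuning
  class(pop) <- c("mt_population", "data.frame")
  pop
}

#' Firing rate of one synthetic neuron
#'
#' Rate in spikes/ms at times `tau` (ms after stimulus onset) for
#' preference-relative strengths `c_dir`, `c_dep` in \[-1, 1\] (positive =
#' the neuron's preferred direction/depth).  The rate is
#' `baseline + (dir_gain * c_dir + depth_gain * c_dep) * (1 + A * exp(-(tau - latency)/tau_tr))`
#' during the stimulus-driven window `[latency, 500 + latency)` and
#' baseline otherwise, clipped at zero (no negative rates).
#'
#' @param spec One row of an [mt_population()] data frame (or any list
#'   with the same fields).
#' @param c_dir,c_dep Signed strengths in \[-1, 1\].
#' @param tau Vector of times (ms, bin starts) within the trial window.
#' @return Numeric vector of rates (spikes/ms), same length as `tau`.
#' @export
neuron_rate <- function(spec, c_dir, c_dep, tau) {
  check_strength(c_dir, "c_dir")
  check_strength(c_dep, "c_dep")
  driven <- tau >= spec$latency & tau < STIM_OFF + spec$latency
  evoked <- (spec$dir_gain * c_dir + spec$depth_gain * c_dep)
  transient <- 1 + spec$transient_amp *
    exp(-(pmax(tau - spec$latency, 0)) / spec$transient_tau)
  r <- spec$baseline_rate + driven * evoked * transient
  pmax(r, 0) / 1000
}

#' Generate a Bernoulli (discrete Poisson) spike train from a rate series
#'
#' Each 1-ms bin independently contains a spike with probability
#' `min(rate * 1 ms, 1)`.
#'
#' @param rate Numeric vector of non-negative rates in spikes/ms.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @return Integer vector of 0/1 spike indicators, same length as `rate`.
#' @export
generate_spike_train <- function(rate, seed = NULL) {
  if (any(!is.finite(rate)) || any(rate < 0)) {
    stop("`rate` must be non-negative", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  p <- pmin(rate, 1)
  as.integer(runif(length(p)) < p)
}

#' Construct a spike-train object
#'
#' A per-trial binary spike indicator series at 1-ms resolution with its
#' metadata.  `bins` must be 0/1 on the standard trial grid
#' ([trial_times()]).
#'
#' @param bins Integer 0/1 vector, one entry per 1-ms bin.
#' @param neuron_id Integer neuron identifier.
#' @param task "direction" or "depth".
#' @param c_dir,c_dep Signed strengths in \[-1, 1\].
#' @param choice "up", "down" or "none".
#' @param times Bin start times; defaults to the standard grid.
#' @return A list of class `spike_train`.
#' @export
spike_train <- function(bins, neuron_id = NA_integer_,
                        task = c("direction", "depth"),
                        c_dir = 0, c_dep = 0,
                        choice = "none", times = trial_times()) {
  task <- match.arg(task)
  bins <- as.integer(bins)
  if (length(bins) != length(times)) {
    stop("`bins` and `times` must have equal length", call. = FALSE)
  }
  if (any(!bins %in% c(0L, 1L))) {
    stop("`bins` must be 0/1 spike indicators", call. = FALSE)
  }
  check_strength(c_dir, "c_dir")
  check_strength(c_dep, "c_dep")
  structure(
    list(bins = bins, times = times, neuron_id = neuron_id, task = task,
         c_dir = c_dir, c_dep = c_dep, choice = choice),
    class = "spike_train"
  )
}

# Truncated Gaussian smoothing kernel: SD 20 ms, support [-60, 60] ms,
# evaluated on the 1-ms grid.  Deliberately NOT renormalized after
# truncation (total mass ~0.9973); rates therefore carry that factor.
kde_kernel <- function(sd = 20, halfwidth = 60) {
  dnorm(seq(-halfwidth, halfwidth), mean = 0, sd = sd)
}

# Convolve a spike-count series (or matrix, column-wise) with the kernel,
# zero-padding the edges so the output lies on the input grid.
kde_smooth <- function(x, kernel = kde_kernel()) {
  hw <- (length(kernel) - 1L) / 2L
  if (is.matrix(x)) {
    pad <- matrix(0, hw, ncol(x))
    y <- stats::filter(rbind(pad, x, pad), kernel, sides = 2)
    y <- y[(hw + 1L):(hw + nrow(x)), , drop = FALSE]
    dimnames(y) <- dimnames(x)
    unclass(y)
  } else {
    pad <- rep(0, hw)
    y <- stats::filter(c(pad, x, pad), kernel, sides = 2)
    as.numeric(y[(hw + 1L):(hw + length(x))])
  }
}

#' Kernel density estimate of a spike train's firing rate
#'
#' Convolves the 0/1 spike indicators with a Gaussian kernel (SD 20 ms)
#' truncated at +/-60 ms and evaluated in 1-ms steps.  The kernel is not
#' renormalized after truncation, so each spike contributes ~0.9973 of a
#' full unit of mass to the rate series.
#'
#' @param train A [spike_train()] object, or a plain 0/1 vector.
#' @return Numeric vector of rates (spikes/ms) on the train's time grid.
#' @export
kde_rate <- function(train) {
  bins <- if (inherits(train, "spike_train")) train$bins else train
  kde_smooth(as.numeric(bins))
}

#' Default stimulus-strength grid
#'
#' Signed strength levels used for both motion coherence and binocular
#' correlation.  Symmetric about zero by construction.
#'
#' @param levels Non-negative magnitudes to sign-expand.
#' @return Sorted numeric vector of signed levels including 0.
#' @export
stimulus_grid <- function(levels = c(0.0625, 0.125, 0.25, 0.5)) {
  sort(unique(c(0, levels, -levels)))
}

#' Build the averaged population rate table ("typical responses")
#'
#' Simulates repeated stimulus presentations for every neuron at every
#' preference-relative condition of the grid, estimates each neuron's
#' rate by kernel density estimation, and averages across neurons,
#' separately for the two tasks.  Because the kernel estimate is linear
#' in spikes, the mean over a neuron's repeats equals the smoothed summed
#' spike train divided by the repeat count; the per-bin summed counts are
#' drawn directly as Binomial(n_repeats, p) which is distributionally
#' identical to summing the individual Bernoulli trains.
#'
#' @param pop An [mt_population()].
#' @param grid Signed strength levels (applied to both axes); must be
#'   symmetric about 0.
#' @param trials_per_condition Repeats per (neuron, condition, task).
#' @param seed Integer seed.
#' @param tasks Character vector of task labels to build.
#' @return An object of class `population_rate_table`: a list with a
#'   4-d array `rates[time, c_dir, c_dep, task]` in spikes/ms plus the
#'   grid metadata.
#' @export
population_rate_table <- function(pop, grid = stimulus_grid(),
                                  trials_per_condition = 20, seed = 1L,
                                  tasks = c("direction", "depth")) {
  stopifnot(inherits(pop, "data.frame"), nrow(pop) >= 1)
  grid <- sort(unique(grid))
  if (!isTRUE(all.equal(grid, sort(-grid)))) {
    stop("`grid` must be symmetric about zero", call. = FALSE)
  }
  tau <- trial_times()
  nt <- length(tau)
  conds <- expand.grid(c_dir = grid, c_dep = grid,
                       KEEP.OUT.ATTRS = FALSE)
  nc <- nrow(conds)

  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  rates <- array(
    0, dim = c(nt, length(grid), length(grid), length(tasks)),
    dimnames = list(NULL, signif(grid, 10), signif(grid, 10), tasks)
  )
  ci <- match(conds$c_dir, grid)
  di <- match(conds$c_dep, grid)

  for (ti in seq_along(tasks)) {
    acc <- matrix(0, nt, nc)
    for (n in seq_len(nrow(pop))) {
      spec <- pop[n, ]
      # probability per 1-ms bin, all conditions at once (nt x nc)
      p <- vapply(seq_len(nc), function(j) {
        pmin(neuron_rate(spec, conds$c_dir[j], conds$c_dep[j], tau), 1)
      }, numeric(nt))
      counts <- matrix(
        rbinom(nt * nc, size = trials_per_condition, prob = p), nt, nc
      )
      acc <- acc + kde_smooth(counts) / trials_per_condition
    }
    acc <- acc / nrow(pop)
    for (j in seq_len(nc)) rates[, ci[j], di[j], ti] <- acc[, j]
  }

  structure(
    list(rates = rates, tau = tau, c_dir_levels = grid,
         c_dep_levels = grid, tasks = tasks,
         n_neurons = nrow(pop),
         trials_per_condition = trials_per_condition,
         seed = as.integer(seed)),
    class = "population_rate_table"
  )
}

#' @export
print.population_rate_table <- function(x, ...) {
  cat("Population rate table:", x$n_neurons, "neurons,",
      length(x$c_dir_levels), "x", length(x$c_dep_levels),
      "strength grid,", length(x$tasks), "task(s),",
      length(x$tau), "time bins\n")
  invisible(x)
}

#' Average spike trains into a population rate table
#'
#' Reference reduction over explicit spike trains: each neuron's mean
#' kernel-density rate is computed per (condition, task) cell, then
#' averaged across neurons.  Every neuron must contribute at least one
#' trial to every cell spanned by the data; a missing cell is an error
#' naming the cell.
#'
#' @param trains A list of [spike_train()] objects.
#' @return A `population_rate_table` (see [population_rate_table()]).
#' @export
average_population_rates <- function(trains) {
  stopifnot(length(trains) >= 1,
            all(vapply(trains, inherits, logical(1), "spike_train")))
  meta <- data.frame(
    neuron_id = vapply(trains, function(t) as.integer(t$neuron_id),
                       integer(1)),
    task = vapply(trains, function(t) t$task, character(1)),
    c_dir = vapply(trains, function(t) t$c_dir, numeric(1)),
    c_dep = vapply(trains, function(t) t$c_dep, numeric(1))
  )
  grid_dir <- sort(unique(meta$c_dir))
  grid_dep <- sort(unique(meta$c_dep))
  tasks <- sort(unique(meta$task))
  neurons <- sort(unique(meta$neuron_id))
  tau <- trains[[1]]$times
  nt <- length(tau)

  rates <- array(
    0, dim = c(nt, length(grid_dir), length(grid_dep), length(tasks)),
    dimnames = list(NULL, signif(grid_dir, 10), signif(grid_dep, 10),
                    tasks)
  )
  for (ti in seq_along(tasks)) {
    for (i in seq_along(grid_dir)) {
      for (j in seq_along(grid_dep)) {
        cell_mean <- matrix(0, nt, length(neurons))
        for (ni in seq_along(neurons)) {
          sel <- which(meta$neuron_id == neurons[ni] &
                       meta$task == tasks[ti] &
                       abs(meta$c_dir - grid_dir[i]) < 1e-9 &
                       abs(meta$c_dep - grid_dep[j]) < 1e-9)
          if (length(sel) == 0L) {
            stop(sprintf(
              "missing cell: neuron %d, task %s, c_dir=%g, c_dep=%g",
              neurons[ni], tasks[ti], grid_dir[i], grid_dep[j]),
              call. = FALSE)
          }
          kds <- vapply(sel, function(s) kde_rate(trains[[s]]),
                        numeric(nt))
          cell_mean[, ni] <- rowMeans(kds)
        }
        rates[, i, j, ti] <- rowMeans(cell_mean)
      }
    }
  }
  structure(
    list(rates = rates, tau = tau, c_dir_levels = grid_dir,
         c_dep_levels = grid_dep, tasks = tasks,
         n_neurons = length(neurons),
         trials_per_condition = NA_integer_, seed = NA_integer_),
    class = "population_rate_table"
  )
}

# Look up the rate series for one (c_dir, c_dep, task) condition.
table_rate <- function(table, c_dir, c_dep, task) {
  stopifnot(inherits(table, "population_rate_table"))
  i <- match_level(c_dir, table$c_dir_levels, "c_dir")
  j <- match_level(c_dep, table$c_dep_levels, "c_dep")
  ti <- match(task, table$tasks)
  if (is.na(ti)) {
    stop(sprintf("task '%s' is not in the table", task), call. = FALSE)
  }
  table$rates[, i, j, ti]
}
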