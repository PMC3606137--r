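# Choice probability: ROC area between spike-count distributions
# conditioned on the subject's choice, after per-condition z-scoring and
# pooling across neurons and conditions, in 100-ms bins across the
# trial, with bootstrap percentile confidence intervals.

#' ROC area between two response distributions
#'
#' The area under the ROC curve separating the preferred-choice and
#' null-choice distributions, computed through the Mann-Whitney
#' identity `P(X_pref > X_null) + 0.5 P(X_pref = X_null)` over all cross
#' pairs (ties get half weight, which equals the trapezoidal ROC area).
#'
#' @param pref,null Numeric response vectors (both non-empty).
#' @return ROC area in \[0, 1\]; 0.5 means no covariation with choice,
#'   1 complete covariation.
#' @export
roc_area <- function(pref, null) {
  n1 <- length(pref)
  n2 <- length(null)
  if (n1 == 0L || n2 == 0L) {
    stop("both response sets must be non-empty", call. = FALSE)
  }
  r <- rank(c(pref, null))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Standardize spike counts within stimulus conditions
#'
#' Z-scores the `count` column within each cell of the grouping keys
#' (default: neuron x task x condition x time bin) using the n-1 SD
#' convention.  Cells with fewer than two trials or zero variance cannot
#' be standardized; their rows are dropped and listed in the `dropped`
#' attribute.
#'
#' @param df Data frame with a `count` column and the grouping columns.
#' @param by Character vector of grouping column names.
#' @return `df` with an added `z` column (zero-variance cells removed).
#' @export
zscore_by_condition <- function(df, by = c("neuron", "task", "c_dir",
                                           "c_dep", "bin_start")) {
  stopifnot("count" %in% names(df), all(by %in% names(df)))
  key <- interaction(df[by], drop = TRUE)
  mu <- ave(df$count, key, FUN = mean)
  s <- ave(df$count, key, FUN = function(x) {
    if (length(x) < 2L) NA_real_ else sd(x)
  })
  z <- (df$count - mu) / s
  bad <- !is.finite(z)
  out <- df[!bad, , drop = FALSE]
  out$z <- z[!bad]
  dropped <- unique(as.character(key[bad]))
  if (length(dropped)) {
    attr(out, "dropped") <- dropped
  }
  out
}

# Preferred choice of each bank neuron in each task: the choice mapped
# to its preference on the task's feature (up <-> up, far <-> up).
bank_preferred_choice <- function(task) {
  spec <- bank_spec()
  if (task == "direction") {
    ifelse(spec$pref_dir == "up", "up", "down")
  } else {
    ifelse(spec$pref_depth == "far", "up", "down")
  }
}

# bootstrap percentile CI of the ROC area by independent resampling
# with replacement from the two pooled standardized distributions
boot_roc_ci <- function(pref, null, n_boot, probs = c(0.025, 0.975)) {
  n1 <- length(pref)
  n2 <- length(null)
  stat <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    stat[b] <- roc_area(pref[sample.int(n1, n1, replace = TRUE)],
                        null[sample.int(n2, n2, replace = TRUE)])
  }
  quantile(stat, probs, names = FALSE)
}

#' Choice-probability time course of the simulated bank neurons
#'
#' Implements the standard CP pipeline on a simulated experiment run
#' with `keep_counts = TRUE`: trial spike counts in eight 100-ms bins
#' (starting -100 to 600 ms after onset) are z-scored per (neuron, task,
#' condition, bin); conditions in which the upward-choice fraction is
#' below 1/4 or above 3/4 are excluded (strict inequalities, so boundary
#' values are retained); standardized counts are pooled across neurons
#' and conditions within each analysis group, split by the neuron's
#' preferred versus null choice in that task, and reduced to an ROC
#' area per bin with a bootstrap percentile confidence interval.
#'
#' Groups: congruent neurons per task ("congruent" x
#' "direction"/"depth"), incongruent neurons by task relation
#' ("incongruent" x "relevant"/"irrelevant", pooled over the two tasks).
#'
#' @param experiment An `lg_trials` data frame from [run_experiment()]
#'   with the `counts` attribute.
#' @param n_boot Bootstrap replicates (default 10000; >= 100).
#' @param seed Seed for the bootstrap.
#' @return A data frame of class `cp_result`, one row per (group,
#'   task_relation, bin): `bin_start`, `group`, `task_relation`, `cp`,
#'   `ci_low`, `ci_high`, `n_pref`, `n_null`.  Bins with no surviving
#'   data carry `NA` cp and a `reason` entry.
#' @export
cp_timecourse <- function(experiment, n_boot = 10000, seed = 1L) {
  counts <- attr(experiment, "counts")
  if (is.null(counts)) {
    stop("`experiment` must be run with keep_counts = TRUE",
         call. = FALSE)
  }
  if (n_boot < 100) stop("`n_boot` must be at least 100", call. = FALSE)
  bins <- as.integer(dimnames(counts)[[3]])
  ntr <- nrow(experiment)

  # condition exclusion on the behavioral up-choice fraction
  key <- interaction(experiment$task, experiment$c_dir, experiment$c_dep,
                     drop = TRUE)
  upfrac <- ave(experiment$choice == "up", key, FUN = mean)
  keep_trial <- upfrac > 1 / 4 & upfrac < 3 / 4

  # long table: trial x neuron x bin
  long <- data.frame(
    trial_row = rep(seq_len(ntr), times = 8L * length(bins)),
    neuron = rep(rep(1:8, each = ntr), times = length(bins)),
    bin_start = rep(bins, each = ntr * 8L),
    count = as.vector(counts)
  )
  long$task <- experiment$task[long$trial_row]
  long$c_dir <- experiment$c_dir[long$trial_row]
  long$c_dep <- experiment$c_dep[long$trial_row]
  long$choice <- experiment$choice[long$trial_row]
  long <- long[keep_trial[long$trial_row], , drop = FALSE]
  if (nrow(long) == 0L) {
    stop("all conditions excluded by the choice-fraction rule",
         call. = FALSE)
  }
  long <- zscore_by_condition(long)

  spec <- bank_spec()
  pref_up <- ifelse(long$task == "direction",
                    spec$pref_dir[long$neuron] == "up",
                    spec$pref_depth[long$neuron] == "far")
  long$is_pref <- (long$choice == "up") == pref_up
  long$group <- ifelse(spec$congruent[long$neuron], "congruent",
                       "incongruent")
  long$task_relation <- ifelse(
    spec$congruent[long$neuron], long$task,
    ifelse(spec$contributes[long$neuron] == long$task, "relevant",
           "irrelevant"))

  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  groups <- unique(long[c("group", "task_relation")])
  groups <- groups[order(groups$group, groups$task_relation), ]
  rows <- list()
  for (gi in seq_len(nrow(groups))) {
    g <- groups$group[gi]
    tr <- groups$task_relation[gi]
    sub <- long[long$group == g & long$task_relation == tr, ]
    for (b in bins) {
      sb <- sub[sub$bin_start == b, ]
      pref <- sb$z[sb$is_pref]
      null <- sb$z[!sb$is_pref]
      if (length(pref) == 0L || length(null) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          bin_start = b, group = g, task_relation = tr,
          cp = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
          n_pref = length(pref), n_null = length(null),
          reason = "no surviving data", stringsAsFactors = FALSE)
        next
      }
      ci <- boot_roc_ci(pref, null, n_boot)
      rows[[length(rows) + 1L]] <- data.frame(
        bin_start = b, group = g, task_relation = tr,
        cp = roc_area(pref, null), ci_low = ci[1], ci_high = ci[2],
        n_pref = length(pref), n_null = length(null),
        reason = NA_character_, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cp_result", "data.frame")
  out
}
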