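# Behavioral analyses: task-wise 4-parameter logistic fits (8 parameters
# over the two tasks), the 9-parameter wrong-task mixture model compared
# by AIC, the switch ratio derived from the fitted sensitivities, and
# Weibull 75%-correct thresholds.

# Aggregate trials into per-condition binomial counts (up successes).
aggregate_up <- function(trials) {
  stopifnot(all(c("c_dir", "c_dep", "choice") %in% names(trials)))
  agg <- aggregate(
    cbind(up = trials$choice == "up", n = 1L),
    by = list(c_dir = trials$c_dir, c_dep = trials$c_dep),
    FUN = sum
  )
  agg
}

bernoulli_loglik <- function(up, n, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(up * log(p) + (n - up) * log(1 - p))
}

#' Fit the 4-parameter logistic choice model for one task
#'
#' Maximum-likelihood logistic regression of the upward-choice
#' probability on the signed stimulus strengths,
#' `p_up = logistic(b0 + b1 C_dir + b2 C_dep + b3 C_dir C_dep)`.
#' `b1` and `b2` are the sensitivities to motion coherence and binocular
#' correlation; the interaction `b3` allows a strong irrelevant stimulus
#' to degrade sensitivity.  Perfect separation is flagged with a warning
#' rather than silently clipped.
#'
#' @param trials A trials data frame (one task) with columns `c_dir`,
#'   `c_dep`, `choice`.
#' @return An object of class `logistic_fit`: coefficients `b0..b3`,
#'   Bernoulli log-likelihood, `vcov`, `converged` and `separation`
#'   flags, task label and trial count.
#' @export
fit_logistic_task <- function(trials) {
  task <- unique(trials$task)
  if (length(task) > 1L) {
    stop("`trials` must contain a single task; see fit_mixture() for a joint fit",
         call. = FALSE)
  }
  agg <- aggregate_up(trials)
  if (nrow(agg) < 2L) {
    stop("need at least two distinct stimulus conditions", call. = FALSE)
  }
  if (all(agg$up == 0) || all(agg$up == agg$n)) {
    stop("both choices must be observed", call. = FALSE)
  }
  fit <- suppressWarnings(
    glm(cbind(up, n - up) ~ c_dir + c_dep + c_dir:c_dep,
        family = binomial(), data = agg)
  )
  beta <- unname(coef(fit))
  p <- plogis(beta[1] + beta[2] * agg$c_dir + beta[3] * agg$c_dep +
                beta[4] * agg$c_dir * agg$c_dep)
  # steep-but-finite psychometric slopes are legitimate; only runaway
  # estimates (IRLS divergence) indicate separation
  separation <- !fit$converged || max(abs(beta)) > 100
  if (separation) {
    warning("possible separation: logistic estimates are unstable",
            call. = FALSE)
  }
  structure(
    list(coef = setNames(beta, c("b0", "b1", "b2", "b3")),
         logLik = bernoulli_loglik(agg$up, agg$n, p),
         vcov = vcov(fit), converged = fit$converged,
         separation = separation,
         task = if (length(task)) task else NA_character_,
         n = sum(agg$n)),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic_fit (%s task, n=%d): ", x$task, x$n))
  cat(paste(names(x$coef), signif(x$coef, 4), sep = "=",
            collapse = ", "),
      sprintf(" lnL=%.2f\n", x$logLik))
  invisible(x)
}

#' Fit both tasks with the eight-parameter logistic model
#'
#' @param trials Trials data frame containing both tasks.
#' @return A list with elements `direction` and `depth`
#'   ([fit_logistic_task()] objects), total `logLik` and `aic`
#'   (`2*8 - 2*lnL`).
#' @export
fit_logistic_both <- function(trials) {
  fits <- lapply(c("direction", "depth"), function(tk) {
    fit_logistic_task(trials[trials$task == tk, ])
  })
  names(fits) <- c("direction", "depth")
  lnL <- fits$direction$logLik + fits$depth$logLik
  c(fits, list(logLik = lnL, aic = 2 * 8 - 2 * lnL))
}

mixture_p_up <- function(beta_dir, beta_dep, p_err, c_dir, c_dep, task) {
  own <- ifelse(task == "direction",
                beta_dir[1] + beta_dir[2] * c_dir + beta_dir[3] * c_dep +
                  beta_dir[4] * c_dir * c_dep,
                beta_dep[1] + beta_dep[2] * c_dir + beta_dep[3] * c_dep +
                  beta_dep[4] * c_dir * c_dep)
  other <- ifelse(task == "direction",
                  beta_dep[1] + beta_dep[2] * c_dir + beta_dep[3] * c_dep +
                    beta_dep[4] * c_dir * c_dep,
                  beta_dir[1] + beta_dir[2] * c_dir + beta_dir[3] * c_dep +
                    beta_dir[4] * c_dir * c_dep)
  (1 - p_err) * plogis(own) + p_err * plogis(other)
}

#' Fit the nine-parameter wrong-task mixture model
#'
#' Joint maximum likelihood over both tasks of
#' `p_up = (1 - p_err) * logistic(own-task linear predictor) +
#' p_err * logistic(other-task linear predictor)`, with four logistic
#' coefficients per task and one shared wrong-task probability `p_err`
#' in \[0, 1\] (8 + 1 = 9 parameters).  Optimized by bounded
#' quasi-Newton (L-BFGS-B) from the eight-parameter solution plus
#' random restarts; because the exact eight-parameter solution with
#' `p_err = 0` is always a candidate, the mixture log-likelihood never
#' falls below the eight-parameter one.
#'
#' @param trials Trials data frame containing both tasks.
#' @param n_restarts Number of random restarts (default 5).
#' @param seed Seed for the restart jitter.
#' @return An object of class `mixture_fit`: `coef_direction`,
#'   `coef_depth`, `p_err`, `logLik`, `aic` (9 parameters), plus the
#'   nested eight-parameter `logLik8`/`aic8` and a `converged` flag.
#' @export
fit_mixture <- function(trials, n_restarts = 5, seed = 1L) {
  base <- fit_logistic_both(trials)
  agg <- lapply(c("direction", "depth"), function(tk) {
    a <- aggregate_up(trials[trials$task == tk, ])
    a$task <- tk
    a
  })
  agg <- do.call(rbind, agg)

  nll <- function(theta) {
    p <- mixture_p_up(theta[1:4], theta[5:8], theta[9],
                      agg$c_dir, agg$c_dep, agg$task)
    -bernoulli_loglik(agg$up, agg$n, p)
  }
  start0 <- c(base$direction$coef, base$depth$coef, 0)
  lower <- c(rep(-Inf, 8), 0)
  upper <- c(rep(Inf, 8), 1)
  run1 <- function(st) {
    tryCatch(
      optim(st, nll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500, factr = 1e7)),
      error = function(e) NULL
    )
  }
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  starts <- c(list(start0, c(start0[1:8], 0.05)),
              lapply(seq_len(max(n_restarts - 2L, 0L)), function(i) {
                c(start0[1:8] * runif(8, 0.5, 1.5), runif(1, 0, 0.3))
              }))
  fits <- Filter(Negate(is.null), lapply(starts, run1))
  if (length(fits) == 0L) {
    stop("mixture fit failed to converge from any start", call. = FALSE)
  }
  vals <- vapply(fits, function(f) f$value, numeric(1))
  best <- fits[[which.min(vals)]]
  lnL <- -best$value
  # never report worse than the nested 8-parameter model at p_err = 0
  if (lnL < base$logLik) {
    best$par <- start0
    lnL <- base$logLik
  }
  structure(
    list(coef_direction = setNames(best$par[1:4],
                                   c("b0", "b1", "b2", "b3")),
         coef_depth = setNames(best$par[5:8],
                               c("b0", "b1", "b2", "b3")),
         p_err = unname(best$par[9]),
         logLik = lnL, aic = 2 * 9 - 2 * lnL,
         logLik8 = base$logLik, aic8 = base$aic,
         converged = best$convergence == 0,
         n = sum(agg$n)),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "mixture_fit: p_err=%.4f, lnL=%.2f, AIC(9)=%.1f vs AIC(8)=%.1f\n",
    x$p_err, x$logLik, x$aic, x$aic8))
  invisible(x)
}

#' Switch ratio from the fitted sensitivities
#'
#' `SR = 0.5 * ((b1_dir - b1_dep)/(b1_dir + b1_dep) +
#' (b2_dep - b2_dir)/(b2_dep + b2_dir))`, where superscripts denote the
#' task the fit comes from: each feature's sensitivity when relevant is
#' contrasted with its sensitivity when irrelevant, normalized by their
#' sum, and the two features are averaged.  SR is exactly 1 when both
#' irrelevant sensitivities are 0 (perfect switching) and exactly 0 when
#' relevant and irrelevant sensitivities are equal (task-oblivious).
#'
#' @param dir_fit,dep_fit [fit_logistic_task()] objects (or bare
#'   coefficient vectors `c(b0, b1, b2, ...)`) for the direction and
#'   depth tasks.
#' @return An object of class `switch_ratio`: `value`, per-feature
#'   components `dir_component`/`dep_component`, and the four
#'   sensitivities.
#' @export
switch_ratio <- function(dir_fit, dep_fit) {
  get_coef <- function(f) if (is.numeric(f)) f else f$coef
  bd <- get_coef(dir_fit)
  bp <- get_coef(dep_fit)
  b1_dir <- bd[2]; b2_dir <- bd[3]
  b1_dep <- bp[2]; b2_dep <- bp[3]
  if (abs(b1_dir + b1_dep) < .Machine$double.eps * 16 ||
      abs(b2_dep + b2_dir) < .Machine$double.eps * 16) {
    stop("switch ratio undefined: zero sensitivity denominator",
         call. = FALSE)
  }
  comp_dir <- (b1_dir - b1_dep) / (b1_dir + b1_dep)
  comp_dep <- (b2_dep - b2_dir) / (b2_dep + b2_dir)
  structure(
    list(value = unname((comp_dir + comp_dep) / 2),
         dir_component = unname(comp_dir),
         dep_component = unname(comp_dep),
         sensitivities = c(b1_dir = unname(b1_dir),
                           b1_dep = unname(b1_dep),
                           b2_dir = unname(b2_dir),
                           b2_dep = unname(b2_dep))),
    class = "switch_ratio"
  )
}

#' @export
print.switch_ratio <- function(x, ...) {
  cat(sprintf("switch ratio: %.3f (direction %.3f, depth %.3f)\n",
              x$value, x$dir_component, x$dep_component))
  invisible(x)
}

#' Fit both tasks and compute the switch ratio
#'
#' Convenience wrapper: [fit_logistic_task()] per task, then
#' [switch_ratio()].
#'
#' @param trials Trials data frame containing both tasks.
#' @return A `switch_ratio` object.
#' @export
sr_from_trials <- function(trials) {
  switch_ratio(fit_logistic_task(trials[trials$task == "direction", ]),
               fit_logistic_task(trials[trials$task == "depth", ]))
}

# correctness with respect to the task-relevant feature; undefined at
# zero relevant strength
trials_correct <- function(trials) {
  c_rel <- ifelse(trials$task == "direction", trials$c_dir, trials$c_dep)
  ok <- c_rel != 0
  list(correct = (trials$choice == "up") == (c_rel > 0) & ok,
       keep = ok, c_rel = c_rel)
}

#' Overall percent correct
#'
#' Fraction of correct choices with respect to the task-relevant
#' feature; trials with zero relevant strength are excluded (correctness
#' undefined there).
#'
#' @param trials Trials data frame.
#' @return Proportion correct in \[0, 1\].
#' @export
percent_correct <- function(trials) {
  tc <- trials_correct(trials)
  mean(tc$correct[tc$keep])
}

# ML fit of the cumulative Weibull  p(c) = 1 - 0.5 exp(-(c/alpha)^beta)
# on binomial (level, n, correct) data; returns alpha, beta.
fit_weibull_pc <- function(level, n, k) {
  nll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    p <- 1 - 0.5 * exp(-(level / a)^b)
    -bernoulli_loglik(k, n, p)
  }
  pc <- k / n
  a0 <- if (any(pc >= 0.75)) level[which(pc >= 0.75)[1]] else max(level)
  starts <- list(c(log(a0), log(1.5)), c(log(max(level)), log(1)),
                 c(log(stats::median(level)), log(2)))
  fits <- lapply(starts, function(s) {
    tryCatch(optim(s, nll, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-10)),
             error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  best <- fits[[which.min(vapply(fits, function(f) f$value, numeric(1)))]]
  list(alpha = exp(best$par[1]), beta = exp(best$par[2]),
       logLik = -best$value)
}

#' 75%-correct psychometric threshold
#'
#' Pools percent correct over the irrelevant strength levels, fits a
#' cumulative Weibull `p = 1 - 0.5 exp(-(c/alpha)^beta)` to percent
#' correct versus absolute relevant strength (zero-strength trials
#' excluded), and returns the strength at which the fit crosses 75%
#' correct, `alpha * log(2)^(1/beta)`.  If performance stays below 75%
#' at every tested level the threshold is flagged `above_max` (and when
#' the extrapolated crossing exceeds the largest tested level it is also
#' flagged); a perfect observer yields a threshold below the smallest
#' tested level, flagged `below_min`.
#'
#' @param trials Trials data frame for one task.
#' @return A list of class `threshold_fit`: `threshold`, `alpha`,
#'   `beta`, `above_max`, `below_min`, and the pooled performance
#'   `curve` (level, n, pct_correct).
#' @export
threshold_75 <- function(trials) {
  tc <- trials_correct(trials)
  lev <- abs(tc$c_rel[tc$keep])
  corr <- tc$correct[tc$keep]
  agg <- aggregate(cbind(k = corr, n = 1L), by = list(level = lev),
                   FUN = sum)
  if (nrow(agg) < 3L) {
    stop("need at least three nonzero relevant-strength levels",
         call. = FALSE)
  }
  fit <- fit_weibull_pc(agg$level, agg$n, agg$k)
  thr <- fit$alpha * log(2)^(1 / fit$beta)
  above <- all(agg$k / agg$n < 0.75) || thr > max(agg$level)
  below <- !above && thr < min(agg$level)
  structure(
    list(threshold = thr, alpha = fit$alpha, beta = fit$beta,
         above_max = above, below_min = below,
         curve = data.frame(level = agg$level, n = agg$n,
                            pct_correct = agg$k / agg$n)),
    class = "threshold_fit"
  )
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat(sprintf("75%% threshold: %.4g%s\n", x$threshold,
              if (x$above_max) " (above tested range)"
              else if (x$below_min) " (below tested range)" else ""))
  invisible(x)
}

#' Per-trial spike counts of each synthetic neuron by strength level
#'
#' Simulates repeated single-feature presentations for every neuron of
#' the population: for the "direction" feature the levels are presented
#' at `c_dep = 0` with both signs (preferred and null), and vice versa.
#' Counts are total spikes over the response window (0 to 600 ms,
#' stimulus plus 100 ms response lag).
#'
#' @param pop An [mt_population()].
#' @param levels Positive strength magnitudes (>= 3 for threshold fits).
#' @param trials_per_level Repeats per (neuron, feature, level, sign).
#' @param seed Integer seed.
#' @return A data frame: `neuron_id`, `feature`, `level`, `sign`
#'   (+1 preferred / -1 null), `trial`, `count`.
#' @export
neuron_level_responses <- function(pop, levels = c(0.0625, 0.125, 0.25, 0.5),
                                   trials_per_level = 30, seed = 1L) {
  stopifnot(all(levels > 0))
  tau <- trial_times()
  win <- tau >= 0 & tau < 600
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  rows <- list()
  for (n in seq_len(nrow(pop))) {
    spec <- pop[n, ]
    for (feat in c("direction", "depth")) {
      for (lv in levels) {
        for (sg in c(1, -1)) {
          cd <- if (feat == "direction") sg * lv else 0
          cp <- if (feat == "direction") 0 else sg * lv
          p <- pmin(neuron_rate(spec, cd, cp, tau), 1)[win]
          counts <- colSums(
            matrix(runif(length(p) * trials_per_level) < p,
                   length(p), trials_per_level)
          )
          rows[[length(rows) + 1L]] <- data.frame(
            neuron_id = spec$id, feature = feat, level = lv, sign = sg,
            trial = seq_len(trials_per_level), count = counts
          )
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Neurometric thresholds from per-level response distributions
#'
#' For each neuron and feature, computes the ROC area between the
#' preferred-sign and null-sign count distributions at each level
#' (ideal-observer accuracy), fits a cumulative Weibull to the (level,
#' ROC) curve by least squares, and reports the 75% threshold.  Neurons
#' with degenerate (constant) responses across all levels are excluded
#' with a log entry.
#'
#' @param responses Data frame from [neuron_level_responses()] (columns
#'   `neuron_id`, `feature`, `level`, `sign`, `count`).
#' @return A data frame with one row per neuron: `neuron_id`,
#'   `threshold_direction`, `threshold_depth`, `excluded`.  Excluded
#'   neurons carry `NA` thresholds; the exclusion log is attached as
#'   attribute `log`.
#' @export
neurometric_threshold <- function(responses) {
  ids <- sort(unique(responses$neuron_id))
  log_lines <- character(0)
  one <- function(id, feat) {
    d <- responses[responses$neuron_id == id & responses$feature == feat, ]
    levels <- sort(unique(d$level))
    if (length(levels) < 3L) {
      stop("need responses at >= 3 levels per feature", call. = FALSE)
    }
    if (sd(d$count) == 0) return(NA_real_)
    auc <- vapply(levels, function(lv) {
      roc_area(d$count[d$level == lv & d$sign > 0],
               d$count[d$level == lv & d$sign < 0])
    }, numeric(1))
    # least-squares Weibull through the (level, ROC) points
    sse <- function(par) {
      a <- exp(par[1]); b <- exp(par[2])
      sum((auc - (1 - 0.5 * exp(-(levels / a)^b)))^2)
    }
    fit <- optim(c(log(max(levels)), log(1.5)), sse,
                 method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
    exp(fit$par[1]) * log(2)^(1 / exp(fit$par[2]))
  }
  thr_dir <- numeric(length(ids))
  thr_dep <- numeric(length(ids))
  for (i in seq_along(ids)) {
    thr_dir[i] <- one(ids[i], "direction")
    thr_dep[i] <- one(ids[i], "depth")
    if (is.na(thr_dir[i]) || is.na(thr_dep[i])) {
      log_lines <- c(log_lines, sprintf(
        "neuron %d excluded: degenerate (constant) responses", ids[i]))
    }
  }
  out <- data.frame(neuron_id = ids, threshold_direction = thr_dir,
                    threshold_depth = thr_dep,
                    excluded = is.na(thr_dir) | is.na(thr_dep))
  attr(out, "log") <- log_lines
  out
}

#' Select a sensitivity-balanced sub-population
#'
#' Sorts neurons by the ratio of direction to depth neurometric
#' thresholds and picks the `k` contiguous neurons (in that order) whose
#' mean ratio is closest to 1, i.e. a sub-population with equal average
#' sensitivity for the two features.
#'
#' @param thresholds Data frame from [neurometric_threshold()].
#' @param k Number of neurons to select (default 40).
#' @return Integer vector of selected `neuron_id`s.
#' @export
select_balanced <- function(thresholds, k = 40) {
  d <- thresholds[!thresholds$excluded, ]
  if (nrow(d) < k) {
    stop(sprintf("only %d usable neurons, cannot select %d", nrow(d), k),
         call. = FALSE)
  }
  ratio <- d$threshold_direction / d$threshold_depth
  ord <- order(ratio)
  d <- d[ord, ]
  ratio <- ratio[ord]
  n_win <- nrow(d) - k + 1L
  means <- vapply(seq_len(n_win), function(i) {
    mean(ratio[i:(i + k - 1L)])
  }, numeric(1))
  i0 <- which.min(abs(means - 1))
  sort(d$neuron_id[i0:(i0 + k - 1L)])
}
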