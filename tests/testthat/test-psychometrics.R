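# Behavioral analyses: logistic and mixture fits, switch ratio,
# Weibull thresholds and the neurometric selection.

test_that("logistic fit recovers known coefficients and the null", {
  beta <- c(0, 10, 2, 0)
  tr <- simulate_choice_data(beta, c(0, 2, 10, 0), n_per_cond = 1000,
                             seed = 41)
  fit <- fit_logistic_task(tr[tr$task == "direction", ])
  se <- sqrt(diag(fit$vcov))
  expect_true(all(abs(fit$coef - beta) < 1.96 * se + 1e-8))
  expect_lte(fit$logLik, 0)

  # stimulus-independent choices: sensitivities near zero
  tr0 <- simulate_choice_data(c(0, 0, 0, 0), c(0, 0, 0, 0),
                              n_per_cond = 500, seed = 42)
  f0 <- fit_logistic_task(tr0[tr0$task == "depth", ])
  se0 <- sqrt(diag(f0$vcov))
  expect_lt(abs(f0$coef["b1"]), 3 * se0[2])
  expect_lt(abs(f0$coef["b2"]), 3 * se0[3])

  # both tasks together make the eight-parameter model
  both <- fit_logistic_both(tr)
  expect_equal(length(both$direction$coef) + length(both$depth$coef), 8)
  expect_equal(both$aic, 16 - 2 * both$logLik)

  expect_error(fit_logistic_task(tr), "single task")
})

test_that("logistic fit flags degenerate inputs", {
  tr <- simulate_choice_data(c(0, 10, 0, 0), c(0, 0, 10, 0),
                             n_per_cond = 20, seed = 43)
  d <- tr[tr$task == "direction", ]
  d_all_up <- d; d_all_up$choice <- "up"
  expect_error(fit_logistic_task(d_all_up), "both choices")
  # perfectly deterministic choices: separation is flagged, not hidden
  d_sep <- d[d$c_dir != 0, ]
  d_sep$choice <- ifelse(d_sep$c_dir > 0, "up", "down")
  expect_warning(fit <- fit_logistic_task(d_sep), "separation")
  expect_true(fit$separation)
})

test_that("switch ratio endpoints and arithmetic are exact", {
  # perfect switching: irrelevant sensitivities zero
  expect_equal(switch_ratio(c(0, 5, 0, 0), c(0, 0, 5, 0))$value, 1)
  # task-oblivious: all four sensitivities equal
  expect_equal(switch_ratio(c(0, 3, 3, 0), c(0, 3, 3, 0))$value, 0)
  # direct arithmetic: 0.5 * (1/3 + 2/4)
  sr <- switch_ratio(c(0, 2, 1, 0), c(0, 1, 3, 0))
  expect_equal(sr$value, (1 / 3 + 2 / 4) / 2, tolerance = 1e-12)
  expect_error(switch_ratio(c(0, 1, 1, 0), c(0, -1, 1, 0)),
               "zero sensitivity")
})

test_that("mixture fit nests the eight-parameter model and recovers p_err", {
  beta_dir <- c(0, 8, 1.5, 0)
  beta_dep <- c(0, 1.5, 8, 0)

  # truth p_err = 0: estimate near zero, mixture never beats by much
  tr0 <- simulate_choice_data(beta_dir, beta_dep, p_err = 0,
                              n_per_cond = 1000, seed = 44)
  m0 <- fit_mixture(tr0)
  expect_gte(m0$logLik, m0$logLik8)        # nesting, always
  expect_lt(m0$p_err, 0.02)
  expect_gte(m0$aic, m0$aic8 - 2)

  # truth p_err = 0.2 with strong sensitivities: recovered in [0.1, 0.3]
  tr2 <- simulate_choice_data(beta_dir, beta_dep, p_err = 0.2,
                              n_per_cond = 1000, seed = 45)
  m2 <- fit_mixture(tr2)
  expect_gte(m2$p_err, 0.1)
  expect_lte(m2$p_err, 0.3)
  # p_err is not redundant here: the mixture clearly beats the plain
  # eight-parameter fit on wrong-task data
  expect_gt(m2$logLik, m2$logLik8)
  expect_equal(m2$aic, 18 - 2 * m2$logLik)
})

test_that("Weibull threshold fits recover truth and flag extremes", {
  # simulate percent correct from a known Weibull
  alpha <- 0.2; beta <- 1.8
  levels <- c(0.0625, 0.125, 0.25, 0.5)
  set.seed(46)
  rows <- lapply(levels, function(lv) {
    p <- 1 - 0.5 * exp(-(lv / alpha)^beta)
    n <- 2000
    correct <- rbinom(n, 1, p)
    # encode as direction-task trials with signed strengths
    data.frame(task = "direction", c_dir = lv * ifelse(correct == 1, 1, -1),
               c_dep = 0, trial = seq_len(n), final_value = NA_real_,
               choice = "up", stringsAsFactors = FALSE)
  })
  tr <- do.call(rbind, rows)
  fit <- threshold_75(tr)
  expect_equal(fit$threshold, alpha * log(2)^(1 / beta), tolerance = 0.03)
  expect_false(fit$above_max)

  # a perfect observer crosses 75% below the smallest tested level
  trp <- tr; trp$c_dir <- abs(trp$c_dir)
  fitp <- threshold_75(trp)
  expect_true(fitp$below_min)
  expect_lt(fitp$threshold, min(levels))

  # chance performance never reaches 75%: flagged above the range
  set.seed(47)
  trc <- tr
  trc$c_dir <- abs(trc$c_dir) * sample(c(-1, 1), nrow(trc), replace = TRUE)
  fitc <- threshold_75(trc)
  expect_true(fitc$above_max)

  expect_error(threshold_75(tr[abs(tr$c_dir) < 0.1, ]), "three nonzero")
})

test_that("confidence intervals from the logistic fit are calibrated", {
  # coverage of the 95% Wald CI for the relevant sensitivity over
  # repeated datasets from a known truth
  beta_dir <- c(0, 6, 1, 0)
  beta_dep <- c(0, 1, 6, 0)
  hits <- vapply(1:100, function(i) {
    tr <- simulate_choice_data(beta_dir, beta_dep, n_per_cond = 200,
                               seed = 1000 + i)
    f <- fit_logistic_task(tr[tr$task == "direction", ])
    se <- sqrt(diag(f$vcov))[2]
    abs(f$coef["b1"] - 6) < 1.96 * se
  }, logical(1))
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.99)
})

test_that("neurometric thresholds mirror tuning and selection balances them", {
  pop <- mt_population(117, seed = 13)
  resp <- neuron_level_responses(pop, trials_per_level = 20, seed = 14)
  thr <- neurometric_threshold(resp)
  expect_equal(nrow(thr), 117)

  # stronger direction tuning on average -> lower direction thresholds
  ok <- !thr$excluded
  expect_lt(median(thr$threshold_direction[ok]),
            median(thr$threshold_depth[ok]))

  sel <- select_balanced(thr, k = 40)
  expect_length(sel, 40)
  sub <- thr[thr$neuron_id %in% sel, ]
  m_dir <- mean(sub$threshold_direction)
  m_dep <- mean(sub$threshold_depth)
  expect_lte(abs(m_dir - m_dep) / mean(c(m_dir, m_dep)), 0.1)

  # degenerate (constant) responses are excluded with a log entry
  resp_flat <- resp[resp$neuron_id %in% 1:4, ]
  resp_flat$count <- ifelse(resp_flat$neuron_id == 2, 5L, resp_flat$count)
  thr_flat <- neurometric_threshold(resp_flat)
  expect_true(thr_flat$excluded[thr_flat$neuron_id == 2])
  expect_match(attr(thr_flat, "log"), "neuron 2", all = FALSE)
})
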