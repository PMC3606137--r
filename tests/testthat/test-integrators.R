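# The general integrator, its four parametrizations, the exact
# gate/leak equivalence and the late-commitment regimes.

test_that("variant constructors enforce their constraints", {
  g <- integrator_config("gated", w = 0.3)
  expect_equal(c(g$k_relevant, g$k_irrelevant), c(0, 0))
  dl <- integrator_config("double_leaky", k = 1 / 110)
  expect_equal(dl$k_relevant, 0)
  expect_equal(dl$k_irrelevant, 1 / 110)
  expect_equal(dl$w, 1)
  sl <- integrator_config("single_leaky", k = 0.01, w = 0.5)
  expect_equal(sl$k_relevant, sl$k_irrelevant)
  tv <- integrator_config("time_varying_gate", k = 1 / 110)
  expect_equal(tv$tau1 - tv$tau0, 500)
  expect_error(integrator_config("gated", w = 1.5), "\\[0, 1\\]")
  expect_error(integrator_config("gated", k = -1), "non-negative")
})

test_that("trial integration accumulates the relevant stream at unit weight", {
  # constant i_rel = 0.01 spikes/ms, i_irr = 0, 500 one-ms steps -> I = 5
  sig <- structure(list(i_dir = rep(0.01, 800), i_dep = rep(0, 800)),
                   class = "differential_signals")
  rec <- integrate_trial(sig, "direction", integrator_config("gated", w = 0))
  expect_equal(rec$final_value, 5, tolerance = 1e-12)
  expect_equal(rec$choice, "up")

  # zero signals: I = 0 and the coin choice is unbiased across seeds
  zero <- structure(list(i_dir = rep(0, 800), i_dep = rep(0, 800)),
                    class = "differential_signals")
  recs <- vapply(1:200, function(s) {
    integrate_trial(zero, "direction", integrator_config("gated"), seed = s)$choice
  }, character(1))
  expect_equal(integrate_trial(zero, "depth",
                               integrator_config("gated"))$final_value, 0)
  p_up <- mean(recs == "up")
  expect_lt(abs(p_up - 0.5), 3 * sqrt(0.25 / 200))
})

test_that("the recursion matches the closed-form decision weights", {
  set.seed(31)
  sig <- structure(
    list(i_dir = round(runif(800, -2, 2), 3),
         i_dep = round(runif(800, -2, 2), 3)),
    class = "differential_signals")
  times <- trial_times()
  for (cfg in list(integrator_config("gated", w = 0.3),
                   integrator_config("time_varying_gate", k = 1 / 110),
                   integrator_config("single_leaky", k = 1 / 80, w = 0.5),
                   integrator_config("double_leaky", k = 1 / 110))) {
    rec <- integrate_trial(sig, "direction", cfg)
    wt <- leakygate:::integration_weights(cfg)
    idx <- match(wt$tau - cfg$step, times)
    oracle <- sum(wt$a_rel * sig$i_dir[idx]) +
      sum(wt$a_irr * sig$i_dep[idx])
    expect_equal(rec$final_value, oracle, tolerance = 1e-9,
                 info = cfg$variant)
  }
})

test_that("double-leaky and time-varying-gate agree exactly on shared trains", {
  tab <- default_table()
  k <- 1 / 110
  runs <- run_experiment_set(
    tab, grid5(),
    list(integrator_config("double_leaky", k = k),
         integrator_config("time_varying_gate", k = k)),
    trials_per_condition = 50, seed = 7)
  expect_equal(max(abs(runs[[1]]$final_value - runs[[2]]$final_value)), 0,
               tolerance = 1e-9)
  expect_identical(runs[[1]]$choice, runs[[2]]$choice)
})

test_that("single-leaky with k = 0 reduces to the gated model trial-for-trial", {
  tab <- default_table()
  runs <- run_experiment_set(
    tab, grid5(),
    list(integrator_config("single_leaky", k = 0, w = 0.4),
         integrator_config("gated", w = 0.4)),
    trials_per_condition = 50, seed = 8)
  expect_identical(runs[[1]]$final_value, runs[[2]]$final_value)
  expect_identical(runs[[1]]$choice, runs[[2]]$choice)
})

test_that("experiments are seed-deterministic and behave sensibly at the null", {
  tab <- default_table()
  cfg <- integrator_config("gated", w = 0.3)
  a <- run_experiment(tab, c(0), cfg, 200, seed = 5)
  b <- run_experiment(tab, c(0), cfg, 200, seed = 5)
  expect_identical(a, b)
  # symmetric null: up fraction near one half
  p_up <- mean(a$choice == "up")
  expect_lt(abs(p_up - 0.5), 3 * sqrt(0.25 / nrow(a)))

  # strong relevant evidence drives the choice
  tr <- run_experiment(tab, grid5(), cfg, 100, seed = 6,
                       tasks = "direction")
  strong <- tr[tr$c_dir == 0.5, ]
  expect_gt(mean(strong$choice == "up"), 0.9)
})

test_that("late commitment regimes reproduce their closed forms and limits", {
  tab <- default_table()
  dl <- integrator_config("double_leaky", k = 1 / 110)
  g1 <- integrator_config("gated", w = 1)

  # t_c at the window start leaves the model unchanged (open regime)
  a <- run_late_commitment(tab, grid5(), dl, t_c = 100, "open", 50, seed = 9)
  b <- run_experiment(tab, grid5(), dl, 50, seed = 9)
  expect_equal(a$final_value, b$final_value)

  # t_c at the window end, open start: every model is a plain
  # unweighted integrator (the w = 1 gated limit)
  a <- run_late_commitment(tab, grid5(), dl, t_c = 600, "open", 50, seed = 10)
  b <- run_experiment(tab, grid5(), g1, 50, seed = 10)
  expect_equal(a$final_value, b$final_value)

  # pre-commitment irrelevant evidence decays by exp(-k (tau1 - t_c)):
  # check the closed form of the open-start weights
  t_c <- 350
  wt <- leakygate:::integration_weights(dl, t_c = t_c, regime = "open")
  pre <- wt$tau <= t_c
  expect_equal(unique(wt$a_irr[pre]), exp(-dl$k * (600 - t_c)))
  expect_equal(wt$a_irr[!pre], exp(-dl$k * (600 - wt$tau[!pre])))
  expect_equal(unique(wt$a_rel), 1)

  # closed start: no integration at all before t_c
  wtc <- leakygate:::integration_weights(dl, t_c = t_c, regime = "closed")
  expect_true(all(wtc$a_rel[wtc$tau <= t_c] == 0))
  expect_true(all(wtc$a_irr[wtc$tau <= t_c] == 0))
  expect_true(all(wtc$a_rel[wtc$tau > t_c] == 1))

  expect_error(
    run_late_commitment(tab, c(0), dl, 300, "sideways", 10, seed = 1),
    "'arg' should be one of|open")
})

test_that("gated switch ratio decreases as the irrelevant weight opens", {
  tab <- default_table()
  ws <- c(0, 0.25, 0.5, 0.75, 1)
  runs <- run_experiment_set(
    tab, grid5(),
    lapply(ws, function(w) integrator_config("gated", w = w)),
    trials_per_condition = 200, seed = 12)
  srs <- vapply(runs, function(tr) sr_from_trials(tr)$value, numeric(1))
  # monotone decreasing along the sweep, allowing Monte-Carlo slack
  expect_true(all(diff(srs) < 0.05))
  expect_gt(srs[1], 0.9)
  expect_lt(srs[5], 0.1)
})
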