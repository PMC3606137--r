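# Synthetic MT population: tuning draws, the parametric rate model, the
# Bernoulli spike front end, kernel rate estimation and the population
# averaging step.

test_that("population generation covers quadrants and favors direction tuning", {
  pop <- mt_population(117, seed = 1)
  expect_equal(nrow(pop), 117)
  quads <- table(pop$pref_dir, pop$pref_depth)
  expect_true(all(quads > 0))
  expect_gt(mean(pop$dir_gain), mean(pop$depth_gain))

  # round-robin assignment: four neurons cover all four quadrants once
  pop4 <- mt_population(4, seed = 0)
  expect_equal(sort(paste(pop4$pref_dir, pop4$pref_depth)),
               c("down far", "down near", "up far", "up near"))

  # deterministic for a fixed seed
  expect_identical(mt_population(20, seed = 5), mt_population(20, seed = 5))

  expect_error(mt_population(0), "positive count")
})

test_that("balanced tuning config equalizes mean gains", {
  pop <- mt_population(40, seed = 2, mt_tuning_defaults(balanced = TRUE))
  ratio <- mean(pop$dir_gain) / mean(pop$depth_gain)
  expect_gte(ratio, 0.9)
  expect_lte(ratio, 1.1)
})

test_that("neuron rate model: baseline, step tuning, clipping, monotonicity", {
  spec <- list(baseline_rate = 10, dir_gain = 40, depth_gain = 20,
               latency = 100, transient_amp = 0, transient_tau = 80)
  # before latency only baseline
  expect_equal(neuron_rate(spec, 0.5, -0.5, tau = 0), 10 / 1000)
  # direct arithmetic: 10 + 40*0.5 = 30 spikes/s
  expect_equal(neuron_rate(spec, 0.5, 0, tau = 200), 0.030)
  # 10 - 40 - 20 = -50 clipped at zero
  expect_equal(neuron_rate(spec, -1, -1, tau = 200), 0)
  expect_error(neuron_rate(spec, 1.5, 0, tau = 200), "\\[-1, 1\\]")

  # monotone non-decreasing in each strength at fixed driven tau
  pop <- mt_population(12, seed = 3)
  cs <- seq(-1, 1, by = 0.25)
  for (n in seq_len(nrow(pop))) {
    r_dir <- vapply(cs, function(c) neuron_rate(pop[n, ], c, 0.2, 300),
                    numeric(1))
    r_dep <- vapply(cs, function(c) neuron_rate(pop[n, ], -0.2, c, 300),
                    numeric(1))
    expect_true(all(diff(r_dir) >= 0))
    expect_true(all(diff(r_dep) >= 0))
  }
})

test_that("Bernoulli spike generator honors rates and clipping", {
  expect_identical(generate_spike_train(rep(0, 100), seed = 1),
                   rep(0L, 100))
  # probability clipped at 1: a >1 spikes/ms bin always spikes
  expect_identical(generate_spike_train(c(1.5, 0), seed = 2)[1], 1L)
  expect_error(generate_spike_train(c(0.1, -0.2)), "non-negative")
  expect_identical(generate_spike_train(rep(0.3, 50), seed = 9),
                   generate_spike_train(rep(0.3, 50), seed = 9))

  # Binomial(500, 0.05) count statistics over many repeats
  set.seed(4)
  counts <- colSums(matrix(runif(500 * 10000) < 0.05, 500, 10000))
  expect_lt(abs(mean(counts) - 25), 3 * sd(counts) / sqrt(10000))
  # variance ~ n p (1 - p) (binomial thinning of the discretization)
  expect_lt(abs(var(counts) - 500 * 0.05 * 0.95), 1.5)
})

test_that("kernel rate estimate: support, symmetry and mass", {
  z <- kde_rate(rep(0L, 800))
  expect_equal(z, rep(0, 800))

  tau <- trial_times()
  bins <- rep(0L, 800)
  bins[which(tau == 300)] <- 1L
  r <- kde_rate(spike_train(bins))
  expect_true(all(r[abs(tau - 300) > 60] == 0))
  # symmetric about the spike
  on_l <- r[match(300 - 1:60, tau)]
  on_r <- r[match(300 + 1:60, tau)]
  expect_equal(on_l, on_r)

  # total mass = spike count x truncated-kernel mass, exactly
  kernel_mass <- sum(dnorm(-60:60, 0, 20))
  expect_equal(sum(r), kernel_mass, tolerance = 1e-9)
  expect_equal(kernel_mass, 0.9973, tolerance = 1e-3)

  bins3 <- rep(0L, 800)
  bins3[match(c(150, 300, 450), tau)] <- 1L
  expect_equal(sum(kde_rate(bins3)), 3 * kernel_mass, tolerance = 1e-9)
})

test_that("averaging spike trains reduces to per-neuron mean KDE rates", {
  tau <- trial_times()
  mk <- function(id, task, cd, cp, bins) {
    spike_train(bins, neuron_id = id, task = task, c_dir = cd, c_dep = cp)
  }
  # one neuron, one trial per condition: table equals its KDE rates
  bins <- as.integer(tau %in% c(100, 200, 300))
  tab1 <- average_population_rates(list(
    mk(1, "direction", 0, 0, bins)))
  expect_equal(as.numeric(tab1$rates[, 1, 1, 1]), kde_rate(bins))

  # two neurons with constant-rate trains: mean of the two KDE rates
  set.seed(11)
  b1 <- generate_spike_train(rep(0.01, 800))
  b2 <- generate_spike_train(rep(0.03, 800))
  tab2 <- average_population_rates(list(
    mk(1, "direction", 0, 0, b1), mk(2, "direction", 0, 0, b2)))
  expect_equal(as.numeric(tab2$rates[, 1, 1, 1]),
               (kde_rate(b1) + kde_rate(b2)) / 2)

  # a neuron missing from one cell is a named error
  expect_error(
    average_population_rates(list(
      mk(1, "direction", 0, 0, b1), mk(2, "direction", 0, 0, b2),
      mk(1, "direction", 0.5, 0, b1))),
    "missing cell: neuron 2.*c_dir=0.5")
})

test_that("built rate table is monotone in strength and symmetric by preference", {
  tab <- default_table()
  tau <- trial_times()
  late <- tau >= 150 & tau < 500
  r_pos <- leakygate:::table_rate(tab, 0.5, 0, "direction")
  r_neg <- leakygate:::table_rate(tab, -0.5, 0, "direction")
  expect_gt(mean(r_pos[late]), mean(r_neg[late]))
  # all rates non-negative, full symmetric grid present
  expect_true(all(tab$rates >= 0))
  expect_equal(tab$c_dir_levels, sort(-tab$c_dir_levels))

  # preference-symmetric populations give matching tables (up to noise):
  # the preferred-axis rate model is quadrant-free, so an up/far and a
  # down/near population with identical tuning parameters must agree
  pop <- mt_population(8, seed = 7)
  pop_upfar <- pop; pop_upfar$pref_dir <- "up"; pop_upfar$pref_depth <- "far"
  pop_dnnear <- pop; pop_dnnear$pref_dir <- "down"; pop_dnnear$pref_depth <- "near"
  g <- c(-0.5, 0, 0.5)
  t1 <- population_rate_table(pop_upfar, g, 30, seed = 3)
  t2 <- population_rate_table(pop_dnnear, g, 30, seed = 4)
  expect_lt(max(abs(apply(t1$rates, 2:4, mean) -
                    apply(t2$rates, 2:4, mean))), 0.002)
})
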