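---
title: "Gated and leaky integrator models of perceptual task switching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gated and leaky integrator models of perceptual task switching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A subject alternates, trial by trial, between two perceptual
discriminations on the same random-dot stimulus: report the *motion
direction* (up/down) or the *binocular depth* (far/near).  Neurons in
area MT carry both signals at once, and their sensitivity does not
change with the task, so task switching has to happen in the readout.
Behaviorally, switching is good but imperfect: choices are biased by
the task-irrelevant stimulus dimension.  Neurally, "incongruent"
neurons — whose preferred direction and preferred depth map to
*opposite* saccade choices — covary with choices in only one of the two
tasks, and during the task in which they are irrelevant their choice
probability (CP) dips *below* 0.5 late in the trial.

This package implements and compares phenomenological readout models
that can produce both observations.  All of them accumulate two
evidence streams — a task-relevant and a task-irrelevant differential
signal — and decide by the sign of the summed accumulators; they differ
only in how the irrelevant stream is attenuated:

* **gated**: constant weight $w \in [0,1]$ on the irrelevant input;
* **time-varying gate**: weight $w(\tau)=e^{k(\tau-\tau_1)}$ that opens
  exponentially toward 1 at decision time $\tau_1$;
* **single-leaky**: both accumulators leak at rate $k$, constant $w$;
* **double-leaky**: only the irrelevant accumulator leaks, $w=1$.

Per 1-ms step the general accumulators follow

$$I_{rel} \leftarrow I_{rel}\,e^{-k_{rel}\Delta\tau} + i_{rel}(\tau)\,\Delta\tau,
\qquad
I_{irr} \leftarrow I_{irr}\,e^{-k_{irr}\Delta\tau} + w(\tau)\,i_{irr}(\tau)\,\Delta\tau,$$

from $\tau_0$ (100 ms after stimulus onset, when stimulus-driven MT
responses arise) to $\tau_1$ (100 ms after offset), i.e. 500 ms of
integration.  Unrolling the recursion, the contribution of the input at
time $\tau$ to the decision is $e^{-k(\tau_1-\tau)}$ for a leak and
$w(\tau)$ for a gate — so a pure irrelevant-stream leak at rate $k$ and
an exponential gate with the same $k$ weight every spike identically.
That is the central equivalence of the model family, and the package
preserves it *exactly* in discrete time by using the per-step decay
factor $e^{-k\Delta\tau}$ rather than a forward-Euler approximation:
`run_experiment_set()` evaluates both variants on shared spike trains
and produces bit-identical decisions.

## The synthetic MT world

The original recordings (117 MT neurons, two macaques) are not public,
so the package generates a synthetic stand-in (`mt_population()`,
`population_rate_table()`) that reproduces the features the models
rely on, and nothing more:

* joint direction x depth tuning, linear in the signed,
  preference-relative strengths, with rates clipped at zero;
* a response latency of about 100 ms (drawn per neuron, 100 ± 8 ms,
  truncated to 60–160 ms) and an onset transient (multiplicative
  amplitude 0.3–0.7 decaying with a 50–150 ms constant) so that rate
  time courses are not flat;
* Poisson-like variability: each 1-ms bin spikes independently with
  probability $\min(r\cdot 1\,\mathrm{ms}, 1)$;
* stronger direction than depth tuning on average: gain means of 40
  and 20 spikes/s per unit strength.  Gains are lognormal with
  substantial scatter (sdlog 0.5), so that — as in real MT — a
  minority of neurons is depth-dominant.  This heterogeneity is what
  makes `select_balanced()` meaningful: a 40-neuron subset with equal
  average direction and depth sensitivity exists inside a
  direction-dominant population;
* baseline rates gamma-distributed around 20 spikes/s.

Preference quadrants (up/far, down/far, up/near, down/near) are
assigned round-robin so even tiny populations cover all four types.
The default stimulus grid places both signed strengths at
$\{0, \pm 0.0625, \pm 0.125, \pm 0.25, \pm 0.5\}$; the paper-style
experiments in the tests use the 5-level subset
$\{0, \pm 0.125, \pm 0.5\}$.

The "typical responses" table averages, separately per task, each
neuron's mean kernel-density rate per preference-relative condition
(Gaussian kernel, SD 20 ms, truncated at ±60 ms, evaluated in 1-ms
steps).  Two deliberate numerical choices:

* the truncated kernel is **not** renormalized — the literal ±3 SD
  support keeps ~99.73% of the mass, and the 0.27% loss is carried
  through consistently;
* because the kernel estimate is linear in spikes, the mean over a
  neuron's repeats equals the smoothed *summed* spike train divided by
  the repeat count, and the per-bin summed count is Binomial(n, p).
  `population_rate_table()` draws those sums directly, which is
  distributionally identical to summing individual Bernoulli trains
  and an order of magnitude faster; `average_population_rates()` is
  the reference reduction over explicit trains.

The exact reduction formula (mean over neurons of per-neuron mean KDE
rates per preferred-axis condition) is a reconstruction from the
surrounding description of the averaging procedure; the original
display is not machine-readable.  The same caveat applies to the
differential-signal formulas below and to the switch-ratio formula.

What a green test on this world does **not** establish: anything about
temporal spike correlations (the front end is Bernoulli-independent by
construction, and the CP time course would change materially under
temporally correlated firing), noise correlations between neurons
(assumed absent), non-stationary tuning, or the actual parameter
values fitted to the monkeys (the recorded data would be required; the
canonical published values $w=0.30$, time constant 110 ms, thresholds
10.7%/9.8%, $p_{err}=0.047$ are treated as example parameters only).

## Readout and decision

Eight simulated neurons (two per quadrant) are instantiated from the
averaged table; each reads the table at the stimulus strengths flipped
into its own preference frame.  Congruent neurons (up/far, down/near)
feed both tasks; each incongruent quadrant contributes one neuron to
the direction readout and one to the depth readout.  With congruent
responses halved to balance the two groups, the instantaneous
differential signals are

$$i_{dir} = \tfrac{s_1+s_2}{2} + s_6 - \tfrac{s_7+s_8}{2} - s_4,
\qquad
i_{dep} = \tfrac{s_1+s_2}{2} + s_3 - \tfrac{s_7+s_8}{2} - s_5.$$

This is the unique assignment consistent with the bank's
task-contribution table and the halving rule.  A final value of
exactly zero (possible at the null stimulus) is resolved by a fair
coin from the trial's seeded stream.

## Behavioral analyses

Each task is fitted with a 4-parameter logistic model
($p_{up} = \sigma(\beta_0+\beta_1 C_{dir}+\beta_2 C_{dep}+\beta_3
C_{dir}C_{dep})$; 8 parameters over both tasks), and jointly with a
9-parameter mixture in which the subject applies the *other* task's
rule with probability $p_{err}$.  The mixture uses one shared
$p_{err}$ across tasks — that structure is inferred from the stated
parameter count (8 + 1 = 9).  The 8-parameter solution with
$p_{err}=0$ is always among the optimizer's candidates, so the mixture
log-likelihood never falls below the nested model's, and the AIC
comparison (2·9 − 2lnL vs 2·8 − 2lnL) is meaningful by construction.
Fits operate on per-condition binomial counts (identical likelihood up
to a constant, dramatically faster than per-trial Bernoulli rows).

The switch ratio contrasts each feature's fitted sensitivity when
relevant vs irrelevant,

$$SR = \tfrac12\left(
\frac{\beta_1^{dir}-\beta_1^{dep}}{\beta_1^{dir}+\beta_1^{dep}} +
\frac{\beta_2^{dep}-\beta_2^{dir}}{\beta_2^{dep}+\beta_2^{dir}}
\right),$$

the simplest form meeting both published endpoints: exactly 1 for
perfect switching (irrelevant sensitivities zero) and exactly 0 when
the four sensitivities are equal.  Degenerate denominators raise an
error rather than returning a silent NaN.

Psychometric and neurometric thresholds use the cumulative Weibull
$p = 1 - 0.5\,e^{-(c/\alpha)^\beta}$, reported at the 75%-correct
point $\alpha(\ln 2)^{1/\beta}$; percent correct excludes
zero-relevant-strength trials (correctness is undefined there), and
performance that never reaches (or always exceeds) the criterion is
flagged rather than extrapolated silently.  The 75% criterion is used
for both behavioral and neurometric curves for internal consistency;
the neurometric curve is the per-level ROC area between the
preferred-sign and null-sign count distributions, fitted by least
squares.  `select_balanced()` sorts neurons by the ratio of direction
to depth thresholds and picks the contiguous window of k (default 40)
whose mean ratio is closest to 1.

## Choice probability

`cp_timecourse()` follows the standard recipe: spike counts in eight
100-ms bins (starting −100 … 600 ms), z-scored per (neuron, task,
condition, bin) with the n−1 SD convention (the convention is a
package choice; the source is silent), pooled across neurons and
conditions, split by the neuron's preferred vs null choice in that
task, and reduced to a Mann–Whitney ROC area (ties at half weight).
Conditions whose upward-choice fraction is below 1/4 or above 3/4 are
excluded before pooling — strict inequalities, so boundary values are
retained.  Confidence intervals are 2.5/97.5 bootstrap percentiles
from independent resampling of the two pooled standardized
distributions (resampling after pooling; the alternative —
per-neuron-first resampling — is not what the quoted procedure
describes).  A neuron's preferred choice follows its preference on the
task's own feature (an up/near neuron prefers "up" in the direction
task and "down" in the depth task).

Under the double-leaky model the irrelevant-task incongruent CP shows
the diagnostic *late* negative trough (early evidence decays away and
cannot covary with choice), while the gated model is depressed below
0.5 from the first stimulus-driven bin onward with no trough.  One
caution for interpreting the 100-ms bins: bins before integration
onset and the post-decision bin (start 600 ms) carry no decision
weight and sit at 0.5, and within the driven bins the CP magnitude
also reflects the rate (hence count-SD) profile, not the integration
weight alone.  The acceptance checks therefore compare bins that
overlap the integration window (starts 100–500 ms).

## Calibration and late task commitment

`calibrate_weight()` sweeps $w$ from 0 to 1 in steps of 0.02 and
`calibrate_time_constant()` searches the gate constant over 10–500 ms,
both against the behavioral switch-ratio target of 0.70; every
candidate is evaluated on shared spike trains (exact for these models
because the candidate parameter enters the decision weights linearly),
and the winner is re-simulated with fresh seeds so the reported SR is
out of sample.  On the default synthetic world both land near
$w^*\approx 0.16$–0.18 and $\tau^*\approx 90$ ms; the published values
(0.30, 110 ms) depend on the recorded population and are not asserted.

`run_late_commitment()` models trials in which the subject has not yet
committed to a task when integration starts.  Before the commitment
time $t_c$, either both streams integrate unweighted and leak-free
("open") or neither integrates ("closed"); from $t_c$ the variant's
own regime applies.  Two reconstructions are documented here because
the source describes the outcome, not the equations:

* under the double-leaky model, irrelevant evidence accumulated before
  $t_c$ decays by $e^{-k(\tau_1-t_c)}$ (the closed form of the
  recursion with the leak switched on at $t_c$);
* the time-varying gate re-anchors its schedule to $t_c$,
  $w(\tau)=e^{k(\tau-(t_c+\tau_1-\tau_0))}$.  A schedule fixed to
  $\tau_1$ would leave the gate nearly open for late commitments,
  which contradicts the described behavior (the weight becomes small
  soon after integration starts, and SR grows with commitment delay);
  re-anchoring reproduces it.  Both regimes are supported for all
  variants.

The commitment sweep (`commitment_sweep()`, default $t_c$ from 0 to
600 ms in 50-ms steps, clamped into the integration window) reproduces
the qualitative orderings: open-start gated SR falls as commitment is
delayed; the open-start double-leaky model stays more accurate than
the open-start gated model at mid-range $t_c$ because stored
irrelevant evidence can still be discarded through the leak; and
closed-start thresholds rise as the effective accumulation window
shrinks.

## Tunable parameters at a glance

| parameter | default | units | role |
|---|---|---|---|
| `w` | 0.3 (example) | – | constant gate weight on irrelevant input |
| `k` | 1/110 (example) | 1/ms | leak or gate-opening rate; time constant 110 ms |
| `tau0`, `tau1` | 100, 600 | ms | integration window (onset + 100 to offset + 100) |
| `trials_per_condition` | 1000 | – | simulated trials per (task, condition) cell |
| grid | 0, ±.0625, ±.125, ±.25, ±.5 | – | signed strength levels, both features |
| `dir_gain_mean` / `depth_gain_mean` | 40 / 20 | sp/s per unit | population tuning asymmetry |
| kernel SD / support | 20 / ±60 | ms | rate estimation kernel (not renormalized) |
| `n_boot` | 10000 | – | bootstrap replicates for CP intervals |
| SR target | 0.70 | – | behavioral calibration target |

## Known limitations

The spike front end is Bernoulli-independent per 1-ms bin; temporally
or across-neuron correlated variability, feedback contributions to CP,
reaction-time (free-response) decisions and collapsing bounds are all
out of scope.  Strength lookups in the rate table are exact (no
interpolation), so experiments must run on a subset of the table grid.
The synthetic tuning model is linear with a single latency step; it is
a stand-in for recorded rates, not a fitted model of them.
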