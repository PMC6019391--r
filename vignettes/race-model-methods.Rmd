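---
title: "A rectified race model of the speed-accuracy tradeoff and its neural read-outs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A rectified race model of the speed-accuracy tradeoff and its neural read-outs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(raceSAT)
```

## The decision model

`raceSAT` implements a race between two evidence accumulators, one per
response alternative. On each trial, accumulator $i$ starts at a point drawn
uniformly from $[0, S_z)$ and evolves by the Euler scheme

$$x_i(t + \Delta t) = \max\!\big(x_i(t) + v_i \Delta t + \sigma \sqrt{\Delta t}\, \epsilon_i,\ 0\big),$$

with independent standard-normal noise $\epsilon_i$ per accumulator and
step. The rectification at zero keeps the accumulators non-negative, which
matters because they are also read out as (non-negative) neural quantities.
The first accumulator to reach the boundary $a$ determines the choice; the
reaction time adds a non-decision component drawn uniformly from
$T_{er} \pm S_{T_{er}}/2$. Trials that never cross within the simulation
horizon are recorded as non-responses.

Speed or accuracy instructions and stimulus difficulty define a 2 x 2 cell
structure. In the baseline parameterization the instruction moves the
boundary $a$ and the start-point range $S_z$, while difficulty moves the two
drift rates ($v_\text{correct}$, $v_\text{incorrect}$); $\sigma$, $T_{er}$
and $S_{T_{er}}$ are shared. Because the first-passage process is invariant
to a common scaling of all evidence-scale parameters
($a, S_z, v_\cdot, \sigma$), one parameter per instruction must be fixed to
set the scale; the model variants differ in which parameters are free:

* `model1`: instructions change the boundary only (9 free parameters),
* `model2`: instructions change boundary and start-point range (10),
* `model3`: instructions change start-point range and noise (10).

```{r}
p <- race_params(a = c(accuracy = 1, speed = 0.8),
                 s_z = c(accuracy = 0.4, speed = 0.5),
                 v_correct = c(easy = 1.2, hard = 0.6),
                 v_incorrect = c(easy = 0.1, hard = 0.05),
                 sigma = 0.5, t_er = 0.35, s_ter = 0.3)
design <- data.frame(instruction = rep(c("accuracy", "speed"), each = 2),
                     difficulty = rep(c("easy", "hard"), 2),
                     n_trials = 2000)
trials <- simulate_dataset(p, design, sim_config(dt = 0.01, n_trials = 2000,
                                                 seed = 1))
aggregate(cbind(acc = choice == "correct", rt) ~ instruction + difficulty,
          trials, mean)
```

Simulations are deterministic given a seed: every trial owns an independent
counter-based random substream, so the same trial index reproduces the same
path regardless of how many trials are simulated, and behavioral, MEP and
ERP-style read-outs of the *same* seed replay the identical trajectories.

## The forced-excursion re-expression

A fitted parameter set in which the speed instruction lowers the boundary
can be re-expressed so that the excursion from baseline to threshold is the
same under both instructions: every evidence-scale parameter of the speed
cells is divided by the speed boundary. By the scaling invariance above this
leaves all predicted choices and reaction times unchanged — the package
verifies trial-for-trial identity under common random numbers — but it
*rescales the decision variable itself*, and therefore changes what the
model predicts for neural signals that read the accumulators out directly.

```{r}
tms <- sat_reference_params("tms")   # bundled reference set (TMS study)
forced <- to_forced_excursion(tms)
subset(forced$cells, instruction == "speed")
```

The two bundled reference sets (`"tms"`, `"eeg"`) provide realistic
operating points; the `"tms"` set lives on a proportion-of-median-RT time
unit, the `"eeg"` set in seconds.

## Fitting by quantile maximum probability

`fit_model()` estimates parameters from choice and reaction-time data by
quantile maximum probability: each condition's correct and error RT
distributions are summarized by the 0.1/0.3/0.5/0.7/0.9 quantiles, observed
counts between quantile edges are scored against model-predicted bin masses
(from a large frozen-seed simulation), and the multinomial log-likelihood is
maximized. Error cells with fewer than ten observations collapse to a
median-only split, and cells without errors contribute a single mass bin.

The objective is a Monte-Carlo estimate, so the optimizer must tolerate a
noisy, non-smooth surface. The package uses differential evolution
(`de_optimize()`, rand-to-best/1/bin with jittered mutation factor) on a
coarse simulation surrogate, followed by a bounds-aware Nelder-Mead polish
on the full-resolution objective; both stages share frozen random numbers
so the surface is fixed during optimization. Model variants are compared by
AIC/BIC (`information_criteria()`) and Akaike weights (`akaike_weights()`).

```{r, eval = FALSE}
fit <- fit_model(trials, model_spec("model2"), fit_control(seed = 7))
fit$theta
information_criteria(fit$log_likelihood, fit$k, fit$n_obs)
```

(A full fit takes a few minutes; see the test suite for complete
parameter-recovery runs at the reference operating points.)

## Motor-evoked-potential read-out

During the decision, a stimulation pulse at latency $t$ probes corticospinal
excitability of the two response effectors. The model treats the momentary
accumulator states as the excitability read-out: `predict_mep_signal()`
samples single-trial paths at scheduled latencies and smooths the
correct-minus-incorrect accumulator difference with the same Gaussian kernel
used for the data, stimulus-locked and response-locked. Empirical records
pass through the matching pipeline: `zscore_amplitudes()` standardizes
within muscle x participant x session, `difference_records()` collapses each
stimulated trial to the responding-minus-nonresponding difference, and
`mep_signal()` smooths with a BCa bootstrap band.

The point of the forced-excursion re-expression appears here: speed-cell
predictions are amplified by exactly the inverse speed boundary, so the
free and forced variants — behaviorally indistinguishable — make different
MEP predictions that the data can separate.

## Centroparietal ERP-like read-out

`predict_cpp_traces()` produces single-trial summed-accumulator traces on a
time grid. Non-decision time is split as $T_{er} = t_e + t_r$
(`nondecision_split()`): accumulation starts $t_e$ after stimulus onset,
and continues for $t_r$ after the boundary crossing before the overt
response, after which the trace is censored. Averages respect the censoring
(`censored_average()`): stimulus-locked averages only include trials still
live at each time point, response-locked averages align trials at their
response sample. `fit_scale_and_split()` estimates the amplitude scale and
the $t_e$/$t_r$ split from observed condition averages by a grid-plus-refine
search with the scale solved in closed form.

```{r}
sp <- nondecision_split(0.25, 0.10)   # t_e + t_r = t_er = 0.35
ep <- predict_cpp_traces(p, sp, sim = sim_config(dt = 0.01, n_trials = 200,
                                                 seed = 2),
                         design = design)
avg <- condition_averages(baseline_correct(ep))
names(avg)[1:4]
```

## Statistics for neural comparisons

Three bespoke procedures support the neural analyses:

* `permutation_slope_test()` compares the build-up slope of two groups'
  smoothed signals over a window by relabelling trials; the slope is
  recomputed per permutation on the shared smoothing grid.
* `cluster_amplitude_test()` controls family-wise error for point-by-point
  amplitude differences: candidate clusters are maximal runs where the two
  groups' 90% BCa bands do not overlap, scored by the summed difference
  against a max-abs-cluster-sum permutation null.
* `bootstrap_mse_difference()` tests whether one model variant's neural
  mean-squared error beats another's, with a bias-corrected interval and a
  p-value by interval inversion.

`bca_interval()` implements the underlying bias-corrected-and-accelerated
bootstrap for scalar or vector statistics; the smoothing-specific fast path
is algebraically identical to resampling and re-smoothing.

## Synthetic studies

The synthetic-data module generates complete studies with known ground
truth: `study_design()` fixes the sampling frame (participants, trials per
cell, per-participant non-decision jitter, stimulation windows),
`generate_behavior()` simulates trial tables, `generate_tms_schedule()`
assigns latency-binned pulses with cancellation when the pulse would land
after the response, and `generate_mep_records()` / `generate_cpp_epochs()`
replay the *same* accumulator paths through linear read-out models with
measurement noise (AR(1) in time for the epoch case). Because read-outs
replay the behavioral paths exactly, recovered effects can be traced to the
generating mechanism rather than to sampling differences.

```{r}
des <- study_design(n_participants = 2, n_trials_cell = 30)
beh <- generate_tms_schedule(generate_behavior(p, des,
                                               sim_config(dt = 0.005, seed = 5)),
                             des, seed = 6)
rec <- generate_mep_records(beh, readout_model(), seed = 7)
head(difference_records(zscore_amplitudes(rec)), 3)
```

## Numerical choices

* Step size `dt = 0.01` (behavioral fits) and `0.005` (read-out studies)
  keep the Euler discretization error well below the Monte-Carlo error at
  the sample sizes used; the boundary-crossing step defines the decision
  time.
* Simulation-based objectives always use common random numbers (frozen
  per-trial substreams) so optimization sees a fixed surface and model
  variants are compared on identical noise.
* All quantiles are type-7; permutation p-values use the add-one two-sided
  convention; bootstrap bands clamp the bias-correction inside the
  resolvable range of the resample count.
* File formats are plain CSV/JSON with sidecar metadata recording the time
  unit and seed (`write_trial_table()`, `write_epochs()`,
  `write_report()`), and readers validate units and reject malformed rows.
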