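# raceSAT

Simulation, fitting and neural-signal prediction for a two-accumulator
rectified race model of perceptual decisions under speed/accuracy
instructions.

## The science in brief

When people trade speed against accuracy, the standard account is that a
speed instruction lowers the decision boundary: less evidence is required,
so responses are faster and more error-prone. An alternative account holds
that the *excursion* of the decision variable — the distance from baseline
to threshold — is fixed, and instructions instead change the baseline or
the urgency of accumulation. Behavioral data alone cannot separate these
accounts, because the first-passage process is invariant to a common
rescaling of all evidence-scale parameters: any boundary change can be
re-expressed, trial for trial, as a change in drift, start-point range and
noise with the boundary held fixed.

Neural read-outs of the decision variable break this tie. `raceSAT`
implements both sides of the argument:

* a **rectified race model** — two non-negative accumulators with uniform
  start points, racing to a boundary, plus uniform non-decision time —
  simulated with per-trial random substreams so behavioral and neural
  read-outs replay identical trajectories;
* **quantile maximum probability fitting** of three model variants
  (boundary, boundary + start-point, start-point + noise effects of the
  instruction) with a differential-evolution optimizer and common random
  numbers;
* the **forced-excursion re-expression** `to_forced_excursion()`, which
  converts a fitted boundary effect into the behaviorally identical
  fixed-excursion parameterization — and thereby changes the predicted
  neural signals by a known factor;
* two neural read-out pipelines: a **motor-evoked-potential (MEP)**
  difference signal (accumulator states probed at stimulation times,
  kernel-smoothed, with BCa bootstrap bands, slope permutation tests and
  cluster-based amplitude tests) and a **centroparietal ERP-like signal**
  (summed accumulators, censored stimulus- and response-locked averaging,
  amplitude-scale and non-decision-split fitting);
* a **synthetic-study generator** with known ground truth, and plain-text
  I/O with unit-checked metadata sidecars.

## Worked example

Simulate the bundled reference parameter set (time unit: proportion of the
median reaction time), where the speed instruction lowers the boundary:

```r
library(raceSAT)
p <- sat_reference_params("tms")
design <- data.frame(instruction = rep(c("accuracy", "speed"), each = 2),
                     difficulty = rep(c("easy", "hard"), 2),
                     n_trials = 5000)
trials <- simulate_dataset(p, design,
                           sim_config(dt = 0.01, n_trials = 5000, seed = 11))
aggregate(cbind(acc = choice == "correct", rt) ~ instruction + difficulty,
          trials, function(x) round(mean(x), 3))
#>   instruction difficulty   acc    rt
#> 1    accuracy       easy 0.898 0.952
#> 2       speed       easy 0.883 0.858
#> 3    accuracy       hard 0.832 1.428
#> 4       speed       hard 0.802 1.264
```

Re-express the speed condition with a forced (unit) excursion. Every
evidence-scale parameter of the speed cells is divided by the speed
boundary (0.893 here):

```r
f <- to_forced_excursion(p)
subset(f$cells, instruction == "speed")
#>   instruction difficulty a   s_z v_correct v_incorrect sigma
#> 2       speed       easy 1 0.586      1.43     0.10974 0.559
#> 4       speed       hard 1 0.586      0.71     0.00448 0.559
```

Behavior is unchanged — `simulate_dataset(f, ...)` with the same seed
reproduces `trials` exactly — but the predicted MEP difference signal for
the speed cells is amplified by exactly the inverse boundary:

```r
sch <- data.frame(instruction = rep(c("accuracy", "speed"), each = 50),
                  latency = c(seq(0.05, 1.4, length.out = 50),
                              seq(0.05, 1.15, length.out = 50)))
sim <- sim_config(dt = 0.01, n_trials = 4000, seed = 6)
free   <- predict_mep_signal(p, sch, sim = sim)
forced <- predict_mep_signal(f, sch, sim = sim)
s <- "speed.hard.stimulus"; i <- c(40, 80)
round(free[[s]]$value[i], 3)            #> 0.062 0.202
round(forced[[s]]$value[i], 3)          #> 0.070 0.226
round(forced[[s]]$value[i] / free[[s]]$value[i], 3)   #> 1.12 1.12
```

That factor (1/0.893 = 1.12) is what lets neural data decide between the
two behaviorally indistinguishable accounts.

Fitting works from a plain trial table (columns `instruction`,
`difficulty`, `choice`, `rt`):

```r
fit <- fit_model(trials, model_spec("model2"), fit_control(seed = 7))
fit$theta                                  # named parameter estimates
information_criteria(fit$log_likelihood, fit$k, fit$n_obs)
```

A full fit runs a differential-evolution stage on a coarse simulation
surrogate plus a Nelder-Mead polish and takes a few minutes.

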