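# Shared helpers for the test suite.

# Four-cell single-participant design used by simulation tests.
four_cell_design <- function(n_trials) {
  data.frame(participant_id = 1, session = 1,
             instruction = rep(c("accuracy", "speed"), each = 2),
             difficulty = rep(c("easy", "hard"), 2),
             n_trials = n_trials)
}

# A small, quick parameter set with moderate drifts for cheap simulations.
quick_params <- function() {
  race_params(a = c(accuracy = 1, speed = 0.8),
              s_z = c(accuracy = 0.4, speed = 0.5),
              v_correct = c(easy = 1.2, hard = 0.6),
              v_incorrect = c(easy = 0.1, hard = 0.05),
              sigma = 0.5, t_er = 0.35, s_ter = 0.3)
}

# A deterministic parameter set: negligible noise, point start at zero,
# no non-decision spread. The correct accumulator ramps at v_correct; the
# boundary sits just below 1 so the crossing step is the first one whose
# ramp value reaches 1 (never a floating-point coin flip at the boundary),
# i.e. decision time ceiling(1 / (v * dt)) * dt.
ramp_params <- function(v = 2, vi = 0.5) {
  race_params(a = 0.998, s_z = 0, v_correct = c(easy = v, hard = v),
              v_incorrect = c(easy = vi, hard = vi),
              sigma = 1e-9, t_er = 0.3, s_ter = 0)
}
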