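#' Synthetic study design
#'
#' The sampling plan of the emulated experiments: participant count,
#' trials per design cell and the per-instruction stimulation windows
#' (stimulus-locked, in the parameter unit). The defaults are the study
#' conditions, not tuning knobs.
#'
#' @param n_participants Number of simulated participants.
#' @param n_trials_cell Trials per instruction x difficulty cell and
#'   participant.
#' @param t_er_jitter Relative spread of per-participant non-decision
#'   means (each participant's `t_er` is scaled by a factor drawn
#'   uniformly from `1 +/- t_er_jitter`).
#' @param stim_windows Named list (`accuracy`, `speed`) of length-2 pulse
#'   latency windows.
#' @param n_latency_bins Number of equal-width latency bins per window
#'   (pulses are scheduled by bin, then uniformly within the bin).
#' @return List of class `study_design`.
#' @export
study_design <- function(n_participants = 18, n_trials_cell = 100,
                         t_er_jitter = 0.05,
                         stim_windows = list(accuracy = c(0.0125, 1.5),
                                             speed = c(0.0125, 1.25)),
                         n_latency_bins = 4) {
  stopifnot(n_participants >= 1, n_trials_cell >= 1,
            t_er_jitter >= 0, t_er_jitter < 1,
            all(c("accuracy", "speed") %in% names(stim_windows)))
  structure(list(n_participants = n_participants,
                 n_trials_cell = n_trials_cell,
                 t_er_jitter = t_er_jitter,
                 stim_windows = stim_windows,
                 n_latency_bins = n_latency_bins),
            class = "study_design")
}

#' Neural read-out model
#'
#' Linear observation models linking latent accumulator states to the two
#' synthetic recordings: MEP amplitude of a muscle is
#' `baseline + gain * accumulator + Gaussian noise` at the pulse, and the
#' epoch trace is `gain * summed accumulators + AR(1) noise`.
#'
#' @param mep_baseline,mep_gain,mep_noise_sd MEP read-out parameters.
#' @param cpp_gain,cpp_noise_sd,cpp_ar Epoch read-out parameters
#'   (`cpp_ar` is the lag-1 autocorrelation of the additive noise).
#' @return List of class `readout_model`.
#' @export
readout_model <- function(mep_baseline = 1, mep_gain = 0.8,
                          mep_noise_sd = 0.25,
                          cpp_gain = 1, cpp_noise_sd = 0.15, cpp_ar = 0.8) {
  stopifnot(mep_gain > 0, mep_noise_sd >= 0, cpp_gain > 0,
            cpp_noise_sd >= 0, abs(cpp_ar) < 1)
  structure(list(mep_baseline = mep_baseline, mep_gain = mep_gain,
                 mep_noise_sd = mep_noise_sd, cpp_gain = cpp_gain,
                 cpp_noise_sd = cpp_noise_sd, cpp_ar = cpp_ar),
            class = "readout_model")
}

# Contiguous simulation blocks (participant x cell), the unit of exact
# trial replay: re-running the core simulator with a block's seed and
# index offset reproduces its trials bit for bit.
.behavior_blocks <- function(behavior) {
  b <- attr(behavior, "blocks")
  if (is.null(b)) stop("`behavior` lacks replay blocks; generate it with generate_behavior()")
  b
}

#' Generate synthetic behavior
#'
#' Simulates the full behavioral data set of an emulated study: every
#' participant contributes all four instruction x difficulty cells, with
#' an individual non-decision mean jittered around the group value. The
#' trial table records each trial's simulation index so that neural
#' observation models can replay the identical accumulator paths.
#'
#' @param params Group-level [race_params()].
#' @param design A [study_design()].
#' @param sim A [sim_config()]; `sim$n_trials` is ignored in favor of the
#'   design, and `sim$seed` drives everything.
#' @return Trial table (`participant_id`, `session`, `instruction`,
#'   `difficulty`, `choice`, `rt`, `decision_time`, `tms_latency` absent),
#'   with attributes `unit`, `seed`, `params` and the replay `blocks`.
#' @export
generate_behavior <- function(params, design = study_design(),
                              sim = sim_config(dt = 0.005, seed = 1)) {
  stopifnot(inherits(params, "race_params"), inherits(design, "study_design"))
  ms <- .max_steps(sim)
  jit <- .with_seed(sim$seed,
    runif(design$n_participants, 1 - design$t_er_jitter,
          1 + design$t_er_jitter))
  cells <- params$cells
  rows <- list(); blocks <- list()
  offset <- 0; k <- 0
  for (p in seq_len(design$n_participants)) {
    for (i in seq_len(nrow(cells))) {
      instr <- cells$instruction[i]; dif <- cells$difficulty[i]
      t_er_p <- unname(params$t_er[instr]) * jit[p]
      cond <- cell_params(params, instr, dif)
      n <- design$n_trials_cell
      z <- race_sim_cpp(n, cond$a, cond$s_z, cond$v_correct,
                        cond$v_incorrect, cond$sigma, t_er_p, params$s_ter,
                        sim$dt, ms, sim$seed, offset)
      dec <- ifelse(z$choice == 0L, NA_real_, z$steps * sim$dt)
      k <- k + 1
      rows[[k]] <- data.frame(participant_id = p, session = 1L,
                              instruction = instr, difficulty = dif,
                              choice = .decode_choice(z$choice),
                              rt = dec + z$ndt, decision_time = dec,
                              sim_index = offset + seq_len(n) - 1,
                              stringsAsFactors = FALSE)
      blocks[[k]] <- data.frame(participant_id = p, instruction = instr,
                                difficulty = dif, t_er = t_er_p,
                                offset = offset, n = n)
      offset <- offset + n
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, unit = params$unit, seed = sim$seed, dt = sim$dt,
            max_time = sim$max_time, params = params,
            t_er_by_participant = unname(params$t_er["accuracy"]) * jit,
            blocks = do.call(rbind, blocks))
}

#' Schedule stimulation pulses
#'
#' Assigns every behavioral trial a stimulus-locked pulse latency: a bin
#' of the instruction's stimulation window is drawn uniformly, then a
#' latency uniformly within the bin. Pulses arriving after the trial's
#' response are cancelled (`delivered = FALSE`), as when stimulation is
#' aborted once a response has been detected.
#'
#' @param behavior Trial table from [generate_behavior()].
#' @param design The [study_design()] that produced it.
#' @param seed RNG seed for the latency draws.
#' @return `behavior` with added `tms_latency` and `delivered` columns.
#' @export
generate_tms_schedule <- function(behavior, design = study_design(), seed = 2) {
  stopifnot(inherits(design, "study_design"))
  n <- nrow(behavior)
  lat <- .with_seed(seed, {
    bin <- sample.int(design$n_latency_bins, n, replace = TRUE)
    u <- runif(n)
    vapply(seq_len(n), function(i) {
      w <- design$stim_windows[[behavior$instruction[i]]]
      edges <- seq(w[1], w[2], length.out = design$n_latency_bins + 1)
      edges[bin[i]] + u[i] * (edges[bin[i] + 1] - edges[bin[i]])
    }, numeric(1))
  })
  behavior$tms_latency <- lat
  behavior$delivered <- is.na(behavior$rt) | behavior$rt >= lat
  behavior
}

#' Generate synthetic MEP records
#'
#' Replays each delivered pulse's trial through the identical simulation
#' stream and reads out both muscles at the pulse: the muscle of the
#' eventually chosen response is labelled `responding`, the other
#' `nonresponding`, and each amplitude follows the linear [readout_model()]
#' applied to its accumulator's state (zero before accumulation onset).
#' Only responded trials yield records.
#'
#' @param behavior Scheduled trial table from [generate_tms_schedule()].
#' @param readout A [readout_model()].
#' @param seed RNG seed for the observation noise.
#' @return MEP record table (`trial_id`, `muscle_role`, `tms_latency`,
#'   `amplitude`, plus condition columns), two rows per stimulated trial.
#' @export
generate_mep_records <- function(behavior, readout = readout_model(),
                                 seed = 3) {
  stopifnot(inherits(readout, "readout_model"))
  if (!"tms_latency" %in% names(behavior))
    stop("`behavior` has no pulse schedule; call generate_tms_schedule() first")
  blocks <- .behavior_blocks(behavior)
  params <- attr(behavior, "params")
  sim_seed <- attr(behavior, "seed"); dt <- attr(behavior, "dt")
  ms <- as.integer(round(attr(behavior, "max_time") / dt))
  xc <- xi <- numeric(nrow(behavior))
  ord <- order(behavior$sim_index)
  for (b in seq_len(nrow(blocks))) {
    sel <- ord[blocks$offset[b] + seq_len(blocks$n[b])]
    cond <- cell_params(params, blocks$instruction[b], blocks$difficulty[b])
    z <- race_sample_cpp(blocks$n[b], cond$a, cond$s_z, cond$v_correct,
                         cond$v_incorrect, cond$sigma, blocks$t_er[b],
                         params$s_ter, dt, ms, behavior$tms_latency[sel],
                         sim_seed, blocks$offset[b])
    xc[sel] <- z$x_correct; xi[sel] <- z$x_incorrect
  }
  use <- which(behavior$delivered & behavior$choice %in% c("correct", "incorrect"))
  resp_is_correct <- behavior$choice[use] == "correct"
  x_resp <- ifelse(resp_is_correct, xc[use], xi[use])
  x_non <- ifelse(resp_is_correct, xi[use], xc[use])
  base <- data.frame(trial_id = behavior$sim_index[use],
                     participant_id = behavior$participant_id[use],
                     session = behavior$session[use],
                     instruction = behavior$instruction[use],
                     difficulty = behavior$difficulty[use],
                     rt = behavior$rt[use],
                     tms_latency = behavior$tms_latency[use],
                     stringsAsFactors = FALSE)
  out <- rbind(cbind(base, muscle_role = "responding", x = x_resp),
               cbind(base, muscle_role = "nonresponding", x = x_non))
  out$amplitude <- readout$mep_baseline + readout$mep_gain * out$x +
    .with_seed(seed, rnorm(nrow(out), sd = readout$mep_noise_sd))
  out$x <- NULL
  out <- out[order(out$trial_id, out$muscle_role == "nonresponding"), ]
  rownames(out) <- NULL
  out
}

#' Generate synthetic ERP-like epochs
#'
#' Replays the behavioral trials through the trace simulator with the
#' given non-decision split (so every trial's reaction time matches the
#' behavioral table exactly) and applies the epoch read-out: summed
#' accumulators times `cpp_gain` plus AR(1) noise. Samples after the
#' response stay `NA`.
#'
#' @param behavior Trial table from [generate_behavior()].
#' @param split A [nondecision_split()] applied to every participant's
#'   jittered non-decision mean (`t_r` is held fixed; the sensory part
#'   absorbs the jitter).
#' @param readout A [readout_model()].
#' @param grid Stimulus-locked epoch grid; step must equal the behavioral
#'   simulation step.
#' @param seed RNG seed for the observation noise.
#' @return An [epoch_set()] whose `trials` carry the behavioral columns.
#' @export
generate_cpp_epochs <- function(behavior, split, readout = readout_model(),
                                grid = NULL, seed = 4) {
  stopifnot(inherits(split, "nondecision_split"), inherits(readout, "readout_model"))
  blocks <- .behavior_blocks(behavior)
  params <- attr(behavior, "params")
  sim_seed <- attr(behavior, "seed"); dt <- attr(behavior, "dt")
  ms <- as.integer(round(attr(behavior, "max_time") / dt))
  if (is.null(grid)) grid <- seq(0, 2, by = dt)
  amp <- matrix(NA_real_, nrow(behavior), length(grid))
  rt_tr <- numeric(nrow(behavior)); ch <- character(nrow(behavior))
  ord <- order(behavior$sim_index)
  for (b in seq_len(nrow(blocks))) {
    sel <- ord[blocks$offset[b] + seq_len(blocks$n[b])]
    cond <- cell_params(params, blocks$instruction[b], blocks$difficulty[b])
    t_e <- blocks$t_er[b] - split$t_r
    if (t_e < 0) stop("motor duration exceeds a participant's non-decision mean")
    z <- race_traces_cpp(blocks$n[b], cond$a, cond$s_z, cond$v_correct,
                         cond$v_incorrect, cond$sigma, t_e, params$s_ter,
                         split$t_r, dt, ms, grid, sim_seed, blocks$offset[b])
    amp[sel, ] <- z$trace
    rt_tr[sel] <- z$rt
    ch[sel] <- .decode_choice(z$choice)
  }
  noise <- .with_seed(seed, {
    e <- matrix(rnorm(length(amp), sd = readout$cpp_noise_sd * sqrt(1 - readout$cpp_ar^2)),
                nrow(amp), ncol(amp))
    e[, 1] <- e[, 1] / sqrt(1 - readout$cpp_ar^2)  # stationary start
    for (j in 2:ncol(e)) e[, j] <- readout$cpp_ar * e[, j - 1] + e[, j]
    e
  })
  amp <- readout$cpp_gain * amp + noise   # NA mask survives the arithmetic
  trials <- behavior[, c("participant_id", "session", "instruction",
                         "difficulty", "sim_index")]
  trials$choice <- ch
  trials$rt <- rt_tr
  epoch_set(grid, amp, trials, unit = params$unit)
}
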