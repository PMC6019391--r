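#' Simulation settings
#'
#' @param dt Time step, in the same unit as the reaction times. The studies
#'   emulated here used 1% of the median RT for behavioral fitting of
#'   median-normalized data, 0.5% for motor-signal predictions and 10 ms for
#'   ERP predictions.
#' @param max_time Censoring horizon: trials in which neither accumulator
#'   has reached the boundary by `max_time` (decision time) are labelled
#'   `"none"`.
#' @param n_trials Default number of trials per condition cell.
#' @param record_traces If `TRUE`, [simulate_trial()] stores the full
#'   per-step trajectories of both accumulators.
#' @param seed Integer seed for the simulation stream. Each trial uses a
#'   deterministic substream derived from `(seed, trial index)`, so
#'   common-random-number comparisons across parameter sets are exact and
#'   single trials can be replayed independently of batch size.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(dt = 0.01, max_time = 5, n_trials = 10000,
                       record_traces = FALSE, seed = 1) {
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be positive")
  if (max_time <= 0) stop("`max_time` must be positive")
  if (n_trials < 0) stop("`n_trials` must be >= 0")
  structure(list(dt = dt, max_time = max_time, n_trials = as.integer(n_trials),
                 record_traces = isTRUE(record_traces), seed = as.integer(seed)),
            class = "sim_config")
}

#' Advance both accumulators by one time step
#'
#' Applies the rectified Euler--Maruyama update
#' `x <- max(x + v * dt + sigma * sqrt(dt) * n, 0)` to each accumulator,
#' with independent standard-normal draws. Exposed mainly for didactic and
#' testing purposes; batch simulation runs in compiled code.
#'
#' @param state Numeric length-2 vector `(x_correct, x_incorrect)`, both
#'   `>= 0`.
#' @param cond A [condition_params()] object.
#' @param dt Positive time step.
#' @param noise Length-2 vector of standard-normal draws; defaults to fresh
#'   draws from R's RNG.
#' @return Updated length-2 state vector.
#' @examples
#' cond <- condition_params(1, 0, 1.28, 0.098, 0)
#' step_accumulators(c(0, 0), cond, dt = 0.01)  # (0.0128, 0.00098)
#' @export
step_accumulators <- function(state, cond, dt, noise = rnorm(2)) {
  stopifnot(inherits(cond, "cond_params"))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("invalid simulation config: `dt` must be a positive scalar")
  if (length(state) != 2L || any(state < 0)) stop("`state` must be two values >= 0")
  drift <- c(cond$v_correct, cond$v_incorrect)
  pmax(state + drift * dt + cond$sigma * sqrt(dt) * noise, 0)
}

.max_steps <- function(sim) as.integer(round(sim$max_time / sim$dt))

.choice_labels <- c("none", "correct", "incorrect")

.decode_choice <- function(code) .choice_labels[code + 1L]

#' Simulate a single race trial
#'
#' Runs one trial of the rectified race: start points drawn independently
#' from `U(0, s_z)`, accumulation until the first boundary crossing, and a
#' uniform non-decision time added to the decision time. When both
#' accumulators first cross on the same step the one farther above the
#' boundary wins (exact ties are broken by a fair coin from the trial's
#' substream).
#'
#' @param cond A [condition_params()] object.
#' @param t_er,s_ter Non-decision mean and uniform width.
#' @param sim A [sim_config()]; `sim$record_traces` controls trace storage.
#' @param trial_index Index of the trial's random substream (default 0);
#'   the same `(seed, trial_index)` always reproduces the same trial.
#' @return A list of class `trial_outcome` with elements `choice`
#'   (`"correct"`, `"incorrect"` or `"none"`), `decision_time`, `rt`
#'   (`NA` for `"none"`), `start_correct`, `start_incorrect` and, when
#'   requested, `trace_correct` / `trace_incorrect` (per-step values, `NA`
#'   beyond the crossing step).
#' @export
simulate_trial <- function(cond, t_er, s_ter, sim = sim_config(),
                           trial_index = 0) {
  stopifnot(inherits(cond, "cond_params"), inherits(sim, "sim_config"))
  if (sim$max_time <= max(t_er)) stop("`max_time` must exceed `t_er`")
  ms <- .max_steps(sim)
  if (sim$record_traces) {
    z <- race_record_cpp(1L, cond$a, cond$s_z, cond$v_correct, cond$v_incorrect,
                         cond$sigma, t_er, s_ter, sim$dt, ms, sim$seed, trial_index)
    choice <- .decode_choice(z$choice[1])
    steps <- z$steps[1]
    out <- list(choice = choice,
                decision_time = if (choice == "none") NA_real_ else steps * sim$dt,
                rt = if (choice == "none") NA_real_ else steps * sim$dt + z$ndt[1],
                start_correct = z$trace_correct[1, 1],
                start_incorrect = z$trace_incorrect[1, 1],
                trace_correct = z$trace_correct[1, seq_len(steps + 1)],
                trace_incorrect = z$trace_incorrect[1, seq_len(steps + 1)])
  } else {
    z <- race_sim_cpp(1L, cond$a, cond$s_z, cond$v_correct, cond$v_incorrect,
                      cond$sigma, t_er, s_ter, sim$dt, ms, sim$seed, trial_index)
    choice <- .decode_choice(z$choice[1])
    out <- list(choice = choice,
                decision_time = if (choice == "none") NA_real_ else z$steps[1] * sim$dt,
                rt = if (choice == "none") NA_real_ else z$steps[1] * sim$dt + z$ndt[1],
                start_correct = z$start_correct[1],
                start_incorrect = z$start_incorrect[1])
  }
  structure(out, class = "trial_outcome")
}

#' Simulate a trial table across a design
#'
#' Batch wrapper running [simulate_trial()]'s compiled core for every cell
#' of a design. Each trial receives a globally unique substream index
#' (stored in column `sim_index`), so the identical trajectory can be
#' replayed later, e.g. to attach simulated neural read-outs.
#'
#' @param params A [race_params()] object.
#' @param design Data frame with columns `instruction`, `difficulty`,
#'   `n_trials`; one row per requested cell.
#' @param sim A [sim_config()]; `sim$seed` fixes the whole table.
#' @return A data frame (class `trial_table`) with columns
#'   `participant_id`, `session`, `instruction`, `difficulty`, `choice`,
#'   `rt`, `decision_time`, `sim_index`. `rt` and `decision_time` are `NA`
#'   for non-responses. Attribute `unit` carries the declared time unit.
#' @examples
#' p <- sat_reference_params("tms")
#' des <- data.frame(instruction = "accuracy", difficulty = "hard",
#'                   n_trials = 500)
#' tab <- simulate_dataset(p, des, sim_config(seed = 7))
#' mean(tab$choice == "correct")
#' @export
simulate_dataset <- function(params, design, sim = sim_config()) {
  stopifnot(inherits(params, "race_params"), inherits(sim, "sim_config"))
  need <- c("instruction", "difficulty", "n_trials")
  if (!all(need %in% names(design))) stop("`design` needs columns: ",
                                          paste(need, collapse = ", "))
  bad <- !(design$instruction %in% .instructions) |
         !(design$difficulty %in% .difficulties)
  if (any(bad)) stop("unknown condition label in design row(s): ",
                     paste(which(bad), collapse = ", "))
  ms <- .max_steps(sim)
  offset <- 0
  out <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    n <- as.integer(design$n_trials[i])
    instr <- design$instruction[i]
    cond <- cell_params(params, instr, design$difficulty[i])
    t_er <- unname(params$t_er[instr])
    if (sim$max_time <= t_er) stop("`max_time` must exceed `t_er`")
    if (n > 0) {
      z <- race_sim_cpp(n, cond$a, cond$s_z, cond$v_correct, cond$v_incorrect,
                        cond$sigma, t_er, params$s_ter, sim$dt, ms,
                        sim$seed, offset)
      responded <- z$choice != 0L
      out[[i]] <- data.frame(
        participant_id = 1L, session = 1L,
        instruction = instr, difficulty = design$difficulty[i],
        choice = .decode_choice(z$choice),
        rt = ifelse(responded, z$steps * sim$dt + z$ndt, NA_real_),
        decision_time = ifelse(responded, z$steps * sim$dt, NA_real_),
        sim_index = offset + seq_len(n) - 1,
        stringsAsFactors = FALSE)
    } else {
      out[[i]] <- data.frame(participant_id = integer(0), session = integer(0),
                             instruction = character(0), difficulty = character(0),
                             choice = character(0), rt = numeric(0),
                             decision_time = numeric(0), sim_index = numeric(0),
                             stringsAsFactors = FALSE)
    }
    offset <- offset + n
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "unit") <- params$unit
  attr(res, "seed") <- sim$seed
  class(res) <- c("trial_table", "data.frame")
  res
}
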