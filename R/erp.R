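#' Sensory/motor split of the non-decision time
#'
#' For ERP-style predictions the single non-decision parameter is divided
#' into a sensory delay `t_e` (before accumulation onset) and a motor
#' duration `t_r` (accumulation continues for `t_r` after the boundary is
#' reached, until the response is executed); `t_e + t_r` equals the
#' behavioral non-decision mean.
#'
#' @param t_e Sensory delay, `>= 0`.
#' @param t_r Motor duration, `>= 0`.
#' @return List of class `nondecision_split`.
#' @export
nondecision_split <- function(t_e, t_r) {
  if (t_e < 0 || t_r < 0) stop("`t_e` and `t_r` must be >= 0")
  structure(list(t_e = t_e, t_r = t_r), class = "nondecision_split")
}

#' Construct an epoch set
#'
#' A collection of single-trial time series on a common grid with
#' per-trial reaction times and condition labels; the container for both
#' model-predicted accumulation epochs and ERP-like data.
#'
#' @param times Common time grid (stimulus-locked).
#' @param amplitude Trials x time matrix (`NA` where undefined, e.g. after
#'   the trial's response).
#' @param trials Data frame with one row per trial; must contain `rt`,
#'   usually also `instruction` and `difficulty`.
#' @param unit Time unit label.
#' @return List of class `epoch_set`.
#' @export
epoch_set <- function(times, amplitude, trials, unit = "s") {
  amplitude <- as.matrix(amplitude)
  if (nrow(amplitude) != nrow(trials)) stop("one amplitude row per trial required")
  if (ncol(amplitude) != length(times)) stop("amplitude columns must match `times`")
  if (!"rt" %in% names(trials)) stop("`trials` needs an `rt` column")
  structure(list(times = times, amplitude = amplitude, trials = trials,
                 unit = unit), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("epoch_set: %d trials x %d samples (%.4g..%.4g %s)\n",
              nrow(x$amplitude), length(x$times), min(x$times), max(x$times),
              x$unit))
  invisible(x)
}

#' Model-predicted summed-accumulator epochs
#'
#' Simulates single-trial traces of the summed (correct + incorrect)
#' rectified accumulators, the model counterpart of a centroparietal
#' ERP: the trace is flat at zero until the sensory delay, accumulation
#' then runs until the boundary crossing and continues for the motor
#' duration `t_r`, and the trial's reaction time is onset + decision time
#' + `t_r` (identical in distribution to the behavioral model when
#' `t_e + t_r = t_er`; trial-for-trial identical under the same seed). The
#' uniform non-decision spread applies to the sensory delay. Samples after
#' the trial's response are `NA` (accumulator behavior after the response
#' is left undefined and masked).
#'
#' @param params A [race_params()] object.
#' @param split A [nondecision_split()]; `t_e + t_r` must equal the
#'   parameter set's `t_er` within tolerance (per instruction).
#' @param sim A [sim_config()] (the emulated analyses used 10000 paths per
#'   condition at 10-ms steps).
#' @param design Data frame of cells to simulate (`instruction`,
#'   `difficulty`, optional `n_trials` defaulting to `sim$n_trials`);
#'   defaults to all four cells.
#' @param grid Stimulus-locked output grid; its step should equal `sim$dt`.
#' @return An [epoch_set()]; `trials` carries `instruction`, `difficulty`,
#'   `choice` and `rt`.
#' @export
predict_cpp_traces <- function(params, split, sim = sim_config(dt = 0.01,
                                 n_trials = 10000),
                               design = NULL,
                               grid = seq(-0.2, 2.0, by = sim$dt)) {
  stopifnot(inherits(params, "race_params"), inherits(split, "nondecision_split"))
  if (is.null(design))
    design <- expand.grid(instruction = .instructions,
                          difficulty = .difficulties, stringsAsFactors = FALSE)
  if (is.null(design$n_trials)) design$n_trials <- sim$n_trials
  ms <- .max_steps(sim)
  mats <- list(); trs <- list()
  offset <- 0
  for (i in seq_len(nrow(design))) {
    instr <- design$instruction[i]
    t_er <- unname(params$t_er[instr])
    if (abs(split$t_e + split$t_r - t_er) > 1e-8)
      stop("t_e + t_r must equal t_er (", t_er, ") for instruction ", instr)
    cond <- cell_params(params, instr, design$difficulty[i])
    n <- as.integer(design$n_trials[i])
    z <- race_traces_cpp(n, cond$a, cond$s_z, cond$v_correct, cond$v_incorrect,
                         cond$sigma, split$t_e, params$s_ter, split$t_r,
                         sim$dt, ms, grid, sim$seed, offset)
    mats[[i]] <- z$trace
    trs[[i]] <- data.frame(instruction = instr,
                           difficulty = design$difficulty[i],
                           choice = .decode_choice(z$choice), rt = z$rt,
                           sim_index = offset + seq_len(n) - 1,
                           stringsAsFactors = FALSE)
    offset <- offset + n
  }
  epoch_set(grid, do.call(rbind, mats), do.call(rbind, trs),
            unit = params$unit)
}

#' Per-trial baseline correction
#'
#' Shifts every trial's trace so that its first sample is zero, matching
#' the baseline handling of the summed-accumulator predictions.
#'
#' @param epochs An [epoch_set()].
#' @return The corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (nrow(epochs$amplitude) == 0L) stop("empty epoch set")
  epochs$amplitude <- epochs$amplitude - epochs$amplitude[, 1]
  epochs
}

#' Censored trial averaging
#'
#' Averages single-trial epochs while removing each trial from the average
#' once its response time has been reached: stimulus-locked, a grid time
#' `t` averages only trials with `rt > t`; response-locked, traces are
#' aligned at the response (time 0) and each pre-response time averages
#' the trials that cover it. Points with no surviving trial are masked.
#'
#' @param epochs An [epoch_set()].
#' @param alignment `"stimulus"` or `"response"`.
#' @param resp_grid Response-locked output grid (used only for
#'   `alignment = "response"`); must share the epoch grid's step. Times
#'   after the response (`> 0`) are masked by construction.
#' @param choices Which trials enter the average (default `"correct"`, as
#'   in the emulated analyses; use `c("correct","incorrect")` to include
#'   errors).
#' @return A [race_signal()] with `n_eff` the surviving-trial counts.
#' @export
censored_average <- function(epochs, alignment = c("stimulus", "response"),
                             resp_grid = NULL, choices = "correct") {
  stopifnot(inherits(epochs, "epoch_set"))
  alignment <- match.arg(alignment)
  keep <- if ("choice" %in% names(epochs$trials))
    epochs$trials$choice %in% choices else rep(TRUE, nrow(epochs$trials))
  amp <- epochs$amplitude[keep, , drop = FALSE]
  rt <- epochs$trials$rt[keep]
  if (nrow(amp) == 0L) stop("no trials to average")
  step <- if (length(epochs$times) > 1L) diff(epochs$times[1:2]) else 1
  if (alignment == "stimulus") {
    live <- outer(rt, epochs$times, ">")       # trial survives at grid time
    live[is.na(live)] <- TRUE                  # non-terminating trials persist
    live <- live & !is.na(amp)
    vals <- ifelse(live, amp, 0)
    n_eff <- colSums(live)
    v <- colSums(vals) / ifelse(n_eff > 0, n_eff, NA_real_)
    race_signal(epochs$times, v, n_eff = n_eff, alignment = "stimulus",
                unit = epochs$unit)
  } else {
    if (is.null(resp_grid)) resp_grid <- seq(-1, 0, by = step)
    ok <- !is.na(rt)
    amp <- amp[ok, , drop = FALSE]; rt <- rt[ok]
    if (nrow(amp) == 0L) stop("no responded trials to average")
    # align at the sample nearest each trial's response
    r_idx <- round((rt - epochs$times[1]) / step) + 1L
    u_off <- round(resp_grid / step)
    G <- length(resp_grid)
    sums <- numeric(G); counts <- numeric(G)
    for (i in seq_len(nrow(amp))) {
      idx <- r_idx[i] + u_off
      valid <- idx >= 1L & idx <= ncol(amp) & resp_grid <= 1e-9
      vv <- rep(NA_real_, G)
      vv[valid] <- amp[i, idx[valid]]
      use <- !is.na(vv)
      sums[use] <- sums[use] + vv[use]
      counts[use] <- counts[use] + 1
    }
    v <- sums / ifelse(counts > 0, counts, NA_real_)
    race_signal(resp_grid, v, n_eff = counts, alignment = "response",
                unit = epochs$unit)
  }
}

#' Condition-wise censored averages of an epoch set
#'
#' Splits an epoch set by condition labels and returns the censored
#' averages for both alignments as a flat named signal list, the format
#' consumed by [signal_mse()] and [fit_amplitude_scale()].
#'
#' @inheritParams censored_average
#' @param stim_grid Optional restriction of the stimulus-locked grid.
#' @return Named list of [race_signal()]s,
#'   names `instruction.difficulty.alignment`.
#' @export
condition_averages <- function(epochs, resp_grid = NULL, choices = "correct",
                               stim_grid = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  labs <- paste(epochs$trials$instruction, epochs$trials$difficulty, sep = ".")
  out <- list()
  for (lv in unique(labs)) {
    sub <- epoch_set(epochs$times,
                     epochs$amplitude[labs == lv, , drop = FALSE],
                     epochs$trials[labs == lv, , drop = FALSE],
                     unit = epochs$unit)
    s_stim <- censored_average(sub, "stimulus", choices = choices)
    if (!is.null(stim_grid)) {
      keep <- s_stim$time >= min(stim_grid) - 1e-9 &
              s_stim$time <= max(stim_grid) + 1e-9
      s_stim <- race_signal(s_stim$time[keep], s_stim$value[keep],
                            s_stim$n_eff[keep], alignment = "stimulus",
                            unit = epochs$unit)
    }
    out[[paste0(lv, ".stimulus")]] <- s_stim
    out[[paste0(lv, ".response")]] <- censored_average(sub, "response",
                                                       resp_grid = resp_grid,
                                                       choices = choices)
  }
  out
}

#' Fit the amplitude scale and non-decision split jointly
#'
#' Searches the sensory delay `t_e` (with `t_r = t_er - t_e`) and a single
#' multiplicative amplitude factor shared across all conditions and both
#' alignments, minimizing the total mean squared error between predicted
#' and observed signals. For each candidate split the optimal scale has
#' the closed least-squares form, so the search is one-dimensional: a
#' coarse grid over `t_e` followed by golden-section refinement around the
#' best grid point.
#'
#' @param prediction_generator `function(t_e) -> named signal list`
#'   (matching `observed` names), typically wrapping
#'   [predict_cpp_traces()] + [condition_averages()] with a fixed seed.
#' @param observed Named list of observed [race_signal()]s.
#' @param t_er Total non-decision time being split.
#' @param n_grid Number of coarse grid points over `[0, t_er]` (default 9).
#' @return List with `scale`, `split` (a [nondecision_split()]), `mse` and
#'   `converged`.
#' @export
fit_scale_and_split <- function(prediction_generator, observed, t_er,
                                n_grid = 9) {
  eval_te <- function(te) {
    pred <- prediction_generator(te)
    sc <- tryCatch(fit_amplitude_scale(pred, observed), error = function(e) NA_real_)
    if (!is.finite(sc)) return(list(mse = Inf, scale = NA_real_))
    list(mse = signal_mse(scale_signals(pred, sc), observed), scale = sc)
  }
  tes <- seq(0, t_er, length.out = n_grid)
  res <- lapply(tes, eval_te)
  mses <- vapply(res, `[[`, 0, "mse")
  best <- which.min(mses)
  lo <- tes[max(1, best - 1)]; hi <- tes[min(n_grid, best + 1)]
  converged <- TRUE
  refined <- tryCatch(
    optimize(function(te) eval_te(te)$mse, lower = lo, upper = hi,
             tol = t_er * 1e-3),
    error = function(e) { converged <<- FALSE; NULL })
  if (!is.null(refined) && refined$objective < mses[best]) {
    te <- refined$minimum; final <- eval_te(te)
  } else {
    te <- tes[best]; final <- res[[best]]
  }
  if (!is.finite(final$mse)) converged <- FALSE
  list(scale = final$scale,
       split = nondecision_split(te, t_er - te),
       mse = final$mse, converged = converged)
}
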