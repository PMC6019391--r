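#' Model variant specification
#'
#' The three fitted variants share the 2 x 2 structure (drift rates free
#' across difficulty, accuracy boundary pinned to 1 as the scaling
#' parameter) and differ in which parameter is additionally freed across
#' speed/accuracy instructions: only the boundary (`model1`, 9 free
#' parameters), boundary plus start-point range (`model2`, 10), or boundary
#' plus non-decision time (`model3`, 10).
#'
#' @param name `"model1"`, `"model2"` or `"model3"`.
#' @return A list of class `model_spec` with fields `name`,
#'   `free_across_instructions` and `n_free_parameters`.
#' @export
model_spec <- function(name = c("model2", "model1", "model3")) {
  name <- match.arg(name)
  free <- switch(name, model1 = "a", model2 = c("a", "s_z"),
                 model3 = c("a", "t_er"))
  k <- switch(name, model1 = 9L, model2 = 10L, model3 = 10L)
  structure(list(name = name, free_across_instructions = free,
                 n_free_parameters = k), class = "model_spec")
}

#' Empirical reaction-time quantiles
#'
#' Linear-interpolation (type-7) quantiles used as bin edges for the
#' quantile-based multinomial fit.
#'
#' @param rts Numeric vector of reaction times.
#' @param probs Strictly increasing probabilities in (0, 1); default the
#'   conventional five (0.1, 0.3, 0.5, 0.7, 0.9), which imply nominal bin
#'   masses (0.1, 0.2, 0.2, 0.2, 0.2, 0.1).
#' @return Numeric vector of bin edges.
#' @export
empirical_quantiles <- function(rts, probs = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  rts <- rts[!is.na(rts)]
  if (length(rts) < 2L) stop("need at least 2 observations for quantiles")
  if (any(diff(probs) <= 0) || any(probs <= 0) || any(probs >= 1))
    stop("`probs` must be strictly increasing within (0, 1)")
  unname(quantile(rts, probs, type = 7))
}

.bin_counts <- function(rts, edges) {
  if (is.null(edges)) return(length(rts))
  tabulate(findInterval(rts, edges) + 1L, nbins = length(edges) + 1L)
}

#' Quantile scheme of a trial table
#'
#' Computes, for every instruction-by-difficulty cell, the correct- and
#' error-response quantile edges and the observed counts in the implied
#' bins. Cells with few error trials fall back to coarser binning: below
#' `min_error` errors only the median is used (two bins), with no errors a
#' single error-mass bin remains. Non-responses are excluded.
#'
#' @param data A trial table ([simulate_dataset()] or [read_trial_table()]).
#' @param probs Quantile probabilities, as [empirical_quantiles()].
#' @param min_error Error-count threshold below which error quantiles
#'   collapse to the median (default 10).
#' @return A list of class `quantile_scheme`: per-cell edges and counts,
#'   plus the total responded-trial count.
#' @export
quantile_scheme <- function(data, probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                            min_error = 10) {
  cells <- expand.grid(instruction = .instructions, difficulty = .difficulties,
                       stringsAsFactors = FALSE)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sel <- data$instruction == cells$instruction[i] &
           data$difficulty == cells$difficulty[i] & data$choice != "none"
    rt_c <- data$rt[sel & data$choice == "correct"]
    rt_e <- data$rt[sel & data$choice == "incorrect"]
    if (length(rt_c) < 2L)
      stop("cell ", cells$instruction[i], "/", cells$difficulty[i],
           " has fewer than 2 correct trials")
    edges_c <- empirical_quantiles(rt_c, probs)
    if (length(rt_e) == 0L) {
      edges_e <- NULL
    } else if (length(rt_e) < min_error) {
      edges_e <- empirical_quantiles(rt_e, 0.5)
    } else {
      edges_e <- empirical_quantiles(rt_e, probs)
    }
    out[[i]] <- list(instruction = cells$instruction[i],
                     difficulty = cells$difficulty[i],
                     n_resp = length(rt_c) + length(rt_e),
                     correct = list(edges = edges_c,
                                    counts = .bin_counts(rt_c, edges_c)),
                     incorrect = list(edges = edges_e,
                                      counts = .bin_counts(rt_e, edges_e)))
  }
  structure(list(cells = out, probs = probs,
                 n_obs = sum(vapply(out, `[[`, 0, "n_resp"))),
            class = "quantile_scheme")
}

#' Quantile-based multinomial log-likelihood
#'
#' The objective of quantile maximum probability estimation: observed bin
#' counts scored against model-predicted bin proportions,
#' `sum(N_i * log(max(p_i, eps)))`. Correct- and error-response bins of a
#' condition share the cell total, so their proportions jointly sum to (at
#' most) one.
#'
#' @param observed_counts Integer vector of bin counts.
#' @param predicted_props Matching vector of predicted proportions.
#' @param eps Floor applied to proportions before taking logs (default
#'   1e-10), preventing minus infinity from finite simulation.
#' @return Log-likelihood in nats (larger is better).
#' @export
qmpe_loglik <- function(observed_counts, predicted_props, eps = 1e-10) {
  if (length(observed_counts) != length(predicted_props))
    stop("counts and proportions must have the same length")
  sum(observed_counts * log(pmax(predicted_props, eps)))
}

#' Evaluate the fitting objective for a parameter set
#'
#' Simulates `sim$n_trials` trials per condition cell, converts the
#' simulated reaction times into bin proportions using the scheme's edges
#' (relative to each cell's responded-trial total), and scores the observed
#' counts with [qmpe_loglik()]. The simulation seed comes from `sim`, so
#' for a fixed configuration the objective is a deterministic function of
#' the parameters.
#'
#' @param params A [race_params()] object.
#' @param scheme A [quantile_scheme()] built from the data being fitted.
#' @param sim A [sim_config()].
#' @return Log-likelihood in nats.
#' @export
evaluate_model <- function(params, scheme, sim = sim_config()) {
  stopifnot(inherits(scheme, "quantile_scheme"))
  ms <- .max_steps(sim)
  ll <- 0
  for (i in seq_along(scheme$cells)) {
    cell <- scheme$cells[[i]]
    cond <- cell_params(params, cell$instruction, cell$difficulty)
    t_er <- unname(params$t_er[cell$instruction])
    z <- race_sim_cpp(sim$n_trials, cond$a, cond$s_z, cond$v_correct,
                      cond$v_incorrect, cond$sigma, t_er, params$s_ter,
                      sim$dt, ms, sim$seed, (i - 1) * sim$n_trials)
    rt <- z$steps * sim$dt + z$ndt
    n_resp <- sum(z$choice != 0L)
    if (n_resp == 0L) {
      props_c <- rep(0, length(cell$correct$counts))
      props_e <- rep(0, length(cell$incorrect$counts))
    } else {
      props_c <- .bin_counts(rt[z$choice == 1L], cell$correct$edges) / n_resp
      props_e <- .bin_counts(rt[z$choice == 2L], cell$incorrect$edges) / n_resp
    }
    ll <- ll + qmpe_loglik(cell$correct$counts, props_c) +
      qmpe_loglik(cell$incorrect$counts, props_e)
  }
  ll
}

#' Information criteria
#'
#' @param loglik Log-likelihood in nats.
#' @param k Number of free parameters.
#' @param n Number of observations.
#' @return Named vector `c(aic, bic)` with `aic = -2*loglik + 2*k` and
#'   `bic = -2*loglik + k*log(n)`.
#' @export
information_criteria <- function(loglik, k, n) {
  stopifnot(n >= 1, k >= 1)
  c(aic = -2 * loglik + 2 * k, bic = -2 * loglik + k * log(n))
}

#' Akaike weights
#'
#' Relative weight of evidence for each model:
#' `w_i = exp(-delta_i/2) / sum(exp(-delta_j/2))` with
#' `delta_i = AIC_i - min(AIC)`. Subtracting the minimum keeps the
#' computation overflow-free for arbitrarily large AIC differences.
#'
#' @param aics Numeric vector of AIC values (>= 2 models).
#' @return Weights summing to one, in the order of `aics`.
#' @export
akaike_weights <- function(aics) {
  if (length(aics) < 2L) stop("need at least two models")
  d <- aics - min(aics)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Fitting configuration
#'
#' @param dt,max_time Simulation step and censoring horizon passed to
#'   [sim_config()] (defaults suit median-normalized time: 1% of the median
#'   RT, horizon 5 medians).
#' @param n_sim Trials per condition for the final objective and polish
#'   stage (default 10000).
#' @param n_sim_de Trials per condition during the global search (default
#'   2000; with `dt_de` this defines a cheaper surrogate surface for the
#'   population stage).
#' @param dt_de Simulation step of the global-search surrogate (default
#'   0.02, i.e. twice the polish step).
#' @param de Control list forwarded to [de_optimize()].
#' @param nm_maxit Iterations of the Nelder--Mead polish (default 300).
#' @param seed Seed governing optimizer and frozen objective noise.
#' @param probs Quantile probabilities for [quantile_scheme()].
#' @return List of class `fit_control`.
#' @export
fit_control <- function(dt = 0.01, max_time = 5, n_sim = 10000,
                        n_sim_de = 2000, dt_de = 0.02,
                        de = list(pop = 40, iter = 150),
                        nm_maxit = 300, seed = 1,
                        probs = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  structure(list(dt = dt, max_time = max_time, n_sim = n_sim,
                 n_sim_de = n_sim_de, dt_de = dt_de, de = de,
                 nm_maxit = nm_maxit, seed = as.integer(seed), probs = probs),
            class = "fit_control")
}

# Parameter-vector layout for each model variant. The start-point range is
# fitted in absolute units; the non-decision width as a fraction of
# 2 * t_er so the earliest non-decision time can never go negative. The
# non-decision mean is bounded by the median RT (not the minimum: the
# uniform spread lets the earliest non-decision time lie well below the
# mean, so the mean may exceed the fastest response).
.theta_layout <- function(spec, rt_med) {
  base_v <- c("v_easy_correct", "v_hard_correct", "v_easy_incorrect",
              "v_hard_incorrect")
  nm <- switch(spec$name,
    model1 = c("a_speed", "s_z", base_v, "sigma", "t_er", "s_ter_frac"),
    model2 = c("a_speed", "s_z_accuracy", "s_z_speed", base_v, "sigma",
               "t_er", "s_ter_frac"),
    model3 = c("a_speed", "s_z", base_v, "sigma", "t_er_accuracy",
               "t_er_speed", "s_ter_frac"))
  lower <- setNames(numeric(length(nm)), nm)
  upper <- setNames(numeric(length(nm)), nm)
  for (p in nm) {
    b <- if (p == "a_speed") c(0.2, 2)
    else if (startsWith(p, "s_z")) c(0, 0.95)
    else if (startsWith(p, "v_")) c(0, 10)
    else if (p == "sigma") c(1e-3, 5)
    else if (startsWith(p, "t_er")) c(0, rt_med)
    else c(0, 0.99)  # s_ter_frac
    lower[p] <- b[1]; upper[p] <- b[2]
  }
  list(names = nm, lower = lower, upper = upper)
}

.theta_to_params <- function(theta, spec, unit) {
  th <- setNames(theta, .theta_layout(spec, rt_med = 1)$names)
  a <- c(accuracy = 1, speed = unname(th["a_speed"]))
  s_z <- if (spec$name == "model2")
    c(accuracy = unname(th["s_z_accuracy"]), speed = unname(th["s_z_speed"]))
  else c(accuracy = unname(th["s_z"]), speed = unname(th["s_z"]))
  t_er <- if (spec$name == "model3")
    c(accuracy = unname(th["t_er_accuracy"]), speed = unname(th["t_er_speed"]))
  else c(accuracy = unname(th["t_er"]), speed = unname(th["t_er"]))
  if (any(s_z >= 0.95 * a)) return(NULL)  # infeasible start-point range
  s_ter <- 2 * min(t_er) * unname(th["s_ter_frac"])
  race_params(a = a, s_z = s_z,
              v_correct = c(easy = unname(th["v_easy_correct"]),
                            hard = unname(th["v_hard_correct"])),
              v_incorrect = c(easy = unname(th["v_easy_incorrect"]),
                              hard = unname(th["v_hard_incorrect"])),
              sigma = unname(th["sigma"]), t_er = t_er, s_ter = s_ter,
              unit = unit)
}

.params_to_theta <- function(params, spec) {
  cl <- params$cells
  val <- function(instr, col) cl[[col]][cl$instruction == instr & cl$difficulty == "easy"]
  vdiff <- function(diff, col) cl[[col]][cl$instruction == "accuracy" & cl$difficulty == diff]
  th <- c(a_speed = val("speed", "a"))
  th <- c(th, switch(spec$name,
    model2 = c(s_z_accuracy = val("accuracy", "s_z"), s_z_speed = val("speed", "s_z")),
    c(s_z = val("accuracy", "s_z"))))
  th <- c(th,
          v_easy_correct = vdiff("easy", "v_correct"),
          v_hard_correct = vdiff("hard", "v_correct"),
          v_easy_incorrect = vdiff("easy", "v_incorrect"),
          v_hard_incorrect = vdiff("hard", "v_incorrect"),
          sigma = val("accuracy", "sigma"))
  th <- c(th, if (spec$name == "model3")
    c(t_er_accuracy = unname(params$t_er["accuracy"]),
      t_er_speed = unname(params$t_er["speed"]))
    else c(t_er = unname(params$t_er["accuracy"])))
  frac <- if (min(params$t_er) > 0) params$s_ter / (2 * min(params$t_er)) else 0
  c(th, s_ter_frac = min(unname(frac), 0.99))
}

.check_fit_data <- function(data) {
  for (instr in .instructions) for (diff in .difficulties) {
    n_c <- sum(data$instruction == instr & data$difficulty == diff &
               data$choice == "correct")
    if (n_c < 20)
      stop("cell ", instr, "/", diff, " has ", n_c,
           " correct trials; at least 20 are required for fitting")
  }
  invisible(TRUE)
}

.make_objective <- function(scheme, spec, control, n_sim, unit, lay,
                            dt = control$dt) {
  sim <- sim_config(dt = dt, max_time = control$max_time,
                    n_trials = n_sim, seed = control$seed)
  function(theta) {
    # Nelder-Mead is unconstrained; points outside the box are infeasible
    if (any(theta < lay$lower - 1e-12) || any(theta > lay$upper + 1e-12))
      return(Inf)
    params <- .theta_to_params(theta, spec, unit)
    if (is.null(params)) return(Inf)
    -evaluate_model(params, scheme, sim)
  }
}

.finish_fit <- function(theta, scheme, spec, control, data, converged,
                        optim_info) {
  unit <- attr(data, "unit") %||% "s"
  params <- .theta_to_params(theta, spec, unit)
  sim <- sim_config(dt = control$dt, max_time = control$max_time,
                    n_trials = control$n_sim, seed = control$seed)
  ll <- evaluate_model(params, scheme, sim)
  ic <- information_criteria(ll, spec$n_free_parameters, scheme$n_obs)
  structure(list(parameters = params, spec = spec, log_likelihood = ll,
                 aic = unname(ic["aic"]), bic = unname(ic["bic"]),
                 n_obs = scheme$n_obs, k = spec$n_free_parameters,
                 theta = theta, converged = converged, optim = optim_info,
                 control = control,
                 provenance = list(seed = control$seed,
                                   n_obs = scheme$n_obs,
                                   rt_checksum = round(sum(data$rt, na.rm = TRUE), 6))),
            class = "race_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a model variant by quantile maximum probability estimation
#'
#' Bins the observed correct and error reaction times per condition into
#' quantile-defined bins, and searches for the parameters whose simulated
#' bin proportions maximize the multinomial likelihood. The search runs a
#' differential-evolution stage on a cheaper frozen-noise objective
#' followed by a Nelder--Mead polish at full simulation size. The accuracy
#' boundary is pinned to 1 throughout as the scaling parameter.
#'
#' @param data A trial table containing all four condition cells with at
#'   least 20 correct trials each.
#' @param spec A [model_spec()].
#' @param control A [fit_control()].
#' @return An object of class `race_fit`: fitted [race_params()],
#'   log-likelihood, AIC, BIC, observation count, the raw parameter vector,
#'   optimizer trace and provenance (seed, data checksum). Deterministic
#'   given `control$seed`.
#' @export
fit_model <- function(data, spec = model_spec("model2"),
                      control = fit_control()) {
  stopifnot(inherits(spec, "model_spec"), inherits(control, "fit_control"))
  .check_fit_data(data)
  scheme <- quantile_scheme(data, control$probs)
  rt_med <- median(data$rt, na.rm = TRUE)
  lay <- .theta_layout(spec, rt_med)
  unit <- attr(data, "unit") %||% "s"
  obj_de <- .make_objective(scheme, spec, control, control$n_sim_de, unit, lay,
                            dt = control$dt_de %||% control$dt)
  de <- de_optimize(obj_de, lay$lower, lay$upper,
                    control = c(control$de, list(seed = control$seed)))
  obj <- .make_objective(scheme, spec, control, control$n_sim, unit, lay)
  nm <- optim(de$par, obj, method = "Nelder-Mead",
              control = list(maxit = control$nm_maxit,
                             reltol = 1e-8))
  theta <- setNames(pmin(pmax(nm$par, lay$lower), lay$upper), lay$names)
  .finish_fit(theta, scheme, spec, control, data,
              converged = nm$convergence == 0,
              optim_info = list(de_trace = de$trace, de_evals = de$evals,
                                nm_counts = nm$counts,
                                nm_convergence = nm$convergence))
}

#' Local simplex refinement of a fit
#'
#' Nelder--Mead refinement from existing parameter values, used inside
#' bootstrap loops where a full global search per replicate would be
#' prohibitive. Respects the same bounds and pinned accuracy boundary as
#' [fit_model()]; on non-convergence the best point found so far is
#' returned with `converged = FALSE`.
#'
#' @param data A trial table (typically a resampled one).
#' @param start A `race_fit` or [race_params()] object supplying starting
#'   values.
#' @param spec A [model_spec()]; defaults to the spec of `start` when that
#'   is a fit.
#' @param control A [fit_control()]; `nm_maxit` governs the refinement
#'   length.
#' @return A `race_fit` object.
#' @export
refit_simplex <- function(data, start, spec = NULL, control = fit_control()) {
  if (inherits(start, "race_fit")) {
    spec <- spec %||% start$spec
    start <- start$parameters
  }
  stopifnot(inherits(start, "race_params"), inherits(spec, "model_spec"))
  .check_fit_data(data)
  scheme <- quantile_scheme(data, control$probs)
  rt_med <- median(data$rt, na.rm = TRUE)
  lay <- .theta_layout(spec, rt_med)
  unit <- attr(data, "unit") %||% attr(start, "unit") %||% start$unit
  theta0 <- pmin(pmax(.params_to_theta(start, spec), lay$lower), lay$upper)
  obj <- .make_objective(scheme, spec, control, control$n_sim, unit, lay)
  nm <- optim(theta0, obj, method = "Nelder-Mead",
              control = list(maxit = control$nm_maxit, reltol = 1e-8))
  best <- if (nm$value <= obj(theta0)) nm$par else theta0
  theta <- setNames(pmin(pmax(best, lay$lower), lay$upper), lay$names)
  .finish_fit(theta, scheme, spec, control, data,
              converged = nm$convergence == 0,
              optim_info = list(nm_counts = nm$counts,
                                nm_convergence = nm$convergence))
}

#' @export
print.race_fit <- function(x, ...) {
  cat(sprintf("race_fit [%s]: loglik %.2f, AIC %.1f, BIC %.1f (K=%d, n=%d)%s\n",
              x$spec$name, x$log_likelihood, x$aic, x$bic, x$k, x$n_obs,
              if (x$converged) "" else "  [not converged]"))
  print(x$parameters)
  invisible(x)
}
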