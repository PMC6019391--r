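#' Decision parameters for one condition cell
#'
#' Bundles the evidence-scale parameters of the race for a single
#' instruction-by-difficulty cell: the response boundary, the upper bound of
#' the uniform start-point distribution, the two accumulation rates and the
#' within-trial noise standard deviation.
#'
#' @param a Response boundary (evidence units), `> 0`.
#' @param s_z Upper bound of the uniform start-point distribution
#'   (evidence units), `0 <= s_z < a`. Start points for the correct and
#'   incorrect accumulator are drawn independently from `U(0, s_z)`.
#' @param v_correct,v_incorrect Mean evidence accrued per unit time by the
#'   accumulator supporting the correct / incorrect response, `>= 0`.
#' @param sigma Standard deviation of the accumulation noise per square-root
#'   unit time, `>= 0`. Increments are Euler--Maruyama:
#'   `sigma * sqrt(dt) * N(0, 1)`.
#'
#' @return An object of class `cond_params`.
#' @examples
#' condition_params(a = 1, s_z = 0.447, v_correct = 1.28,
#'                  v_incorrect = 0.098, sigma = 0.499)
#' @export
condition_params <- function(a, s_z, v_correct, v_incorrect, sigma) {
  stopifnot(is.numeric(a), is.numeric(s_z), is.numeric(v_correct),
            is.numeric(v_incorrect), is.numeric(sigma))
  if (a <= 0) stop("boundary `a` must be positive")
  if (s_z < 0 || s_z >= a) stop("`s_z` must satisfy 0 <= s_z < a")
  if (v_correct < 0 || v_incorrect < 0) stop("drift rates must be >= 0")
  if (sigma < 0) stop("`sigma` must be >= 0")
  structure(list(a = a, s_z = s_z, v_correct = v_correct,
                 v_incorrect = v_incorrect, sigma = sigma),
            class = "cond_params")
}

#' @export
print.cond_params <- function(x, ...) {
  cat(sprintf("race condition: A=%.4g, S_z=%.4g, v+=%.4g, v-=%.4g, sigma=%.4g\n",
              x$a, x$s_z, x$v_correct, x$v_incorrect, x$sigma))
  invisible(x)
}

.instructions <- c("accuracy", "speed")
.difficulties <- c("easy", "hard")

#' Full parameter set of the race model across the 2 x 2 design
#'
#' Holds one set of decision parameters per (instruction x difficulty) cell
#' plus the global non-decision terms. The constructor accepts the natural
#' free-excursion structure -- boundaries and start-point ranges per
#' instruction, drift rates per difficulty, a shared noise parameter -- and
#' expands it to per-cell storage, so that re-expressions which break the
#' sharing (such as [to_forced_excursion()]) remain representable.
#'
#' @param a Named vector of boundaries, names `accuracy` and `speed`; or a
#'   single value used for both.
#' @param s_z Named vector (as `a`) of start-point ranges, or single value.
#' @param v_correct,v_incorrect Named vectors of drift rates, names `easy`
#'   and `hard`; or single values.
#' @param sigma Noise standard deviation, single value (or named per
#'   instruction).
#' @param t_er Mean non-decision time (time units); single value, or named
#'   per instruction for variants that free it across instructions.
#' @param s_ter Width of the uniform non-decision distribution; the draw is
#'   `U(t_er - s_ter/2, t_er + s_ter/2)`, so `t_er >= s_ter/2`.
#' @param scaling_reference Which instruction's boundary is the fixed
#'   scaling parameter (conventionally `"accuracy"`, fixed to 1).
#' @param unit Time unit of `t_er`, `s_ter` and all simulated times, e.g.
#'   `"s"`, `"ms"` or `"prop_median_rt"` (times expressed as a proportion of
#'   the median reaction time).
#' @param cells Alternatively, a data frame with columns `instruction`,
#'   `difficulty`, `a`, `s_z`, `v_correct`, `v_incorrect`, `sigma`
#'   (one row per cell), bypassing the shared-structure expansion.
#'
#' @return An object of class `race_params`: a list with elements `cells`
#'   (data frame, 4 rows), `t_er` (named vector over instructions), `s_ter`,
#'   `scaling_reference` and `unit`.
#' @seealso [to_forced_excursion()], [sat_reference_params()]
#' @examples
#' race_params(a = c(accuracy = 1, speed = 0.893),
#'             s_z = c(accuracy = 0.447, speed = 0.523),
#'             v_correct = c(easy = 1.280, hard = 0.634),
#'             v_incorrect = c(easy = 0.098, hard = 0.004),
#'             sigma = 0.499, t_er = 0.382, s_ter = 0.374,
#'             unit = "prop_median_rt")
#' @export
race_params <- function(a = 1, s_z = 0, v_correct = 1, v_incorrect = 0,
                        sigma = 1, t_er = 0, s_ter = 0,
                        scaling_reference = "accuracy",
                        unit = "s", cells = NULL) {
  by_instr <- function(x, what) {
    if (length(x) == 1L && is.null(names(x))) return(setNames(rep(x, 2), .instructions))
    if (!all(.instructions %in% names(x)))
      stop("`", what, "` must be a single value or named over instructions")
    x[.instructions]
  }
  by_diff <- function(x, what) {
    if (length(x) == 1L && is.null(names(x))) return(setNames(rep(x, 2), .difficulties))
    if (!all(.difficulties %in% names(x)))
      stop("`", what, "` must be a single value or named over difficulties")
    x[.difficulties]
  }
  if (is.null(cells)) {
    a <- by_instr(a, "a"); s_z <- by_instr(s_z, "s_z"); sig <- by_instr(sigma, "sigma")
    vc <- by_diff(v_correct, "v_correct"); vi <- by_diff(v_incorrect, "v_incorrect")
    cells <- expand.grid(instruction = .instructions, difficulty = .difficulties,
                         stringsAsFactors = FALSE)
    attr(cells, "out.attrs") <- NULL  # keep the cell table serialization-stable
    cells$a <- unname(a[cells$instruction])
    cells$s_z <- unname(s_z[cells$instruction])
    cells$v_correct <- unname(vc[cells$difficulty])
    cells$v_incorrect <- unname(vi[cells$difficulty])
    cells$sigma <- unname(sig[cells$instruction])
  } else {
    need <- c("instruction", "difficulty", "a", "s_z", "v_correct",
              "v_incorrect", "sigma")
    if (!all(need %in% names(cells))) stop("`cells` must have columns: ",
                                           paste(need, collapse = ", "))
    cells <- cells[, need]
  }
  t_er <- by_instr(t_er, "t_er")
  if (any(t_er < 0) || s_ter < 0) stop("`t_er` and `s_ter` must be >= 0")
  if (any(t_er - s_ter / 2 < 0)) stop("`t_er - s_ter/2` must be >= 0")
  if (!scaling_reference %in% .instructions)
    stop("`scaling_reference` must be one of: ", paste(.instructions, collapse = ", "))
  for (i in seq_len(nrow(cells)))
    condition_params(cells$a[i], cells$s_z[i], cells$v_correct[i],
                     cells$v_incorrect[i], cells$sigma[i])  # validation only
  structure(list(cells = cells, t_er = t_er, s_ter = s_ter,
                 scaling_reference = scaling_reference, unit = unit),
            class = "race_params")
}

#' @export
print.race_params <- function(x, ...) {
  cat("race_params (unit:", x$unit, ")\n")
  print(x$cells, row.names = FALSE)
  cat(sprintf("t_er: %s   s_ter: %.4g   scaling reference: %s\n",
              paste(sprintf("%s=%.4g", names(x$t_er), x$t_er), collapse = ", "),
              x$s_ter, x$scaling_reference))
  invisible(x)
}

#' Extract one cell of a parameter set
#'
#' @param params A [race_params()] object.
#' @param instruction `"accuracy"` or `"speed"`.
#' @param difficulty `"easy"` or `"hard"`.
#' @return A [condition_params()] object.
#' @export
cell_params <- function(params, instruction, difficulty) {
  stopifnot(inherits(params, "race_params"))
  i <- which(params$cells$instruction == instruction &
             params$cells$difficulty == difficulty)
  if (length(i) != 1L) stop("unknown condition cell: ", instruction, "/", difficulty)
  with(params$cells[i, ], condition_params(a, s_z, v_correct, v_incorrect, sigma))
}

#' Re-express parameters under the forced-excursion constraint
#'
#' Divides every evidence-scale parameter (`a`, `s_z`, `v_correct`,
#' `v_incorrect`, `sigma`) of the cells belonging to `reference_cell`'s
#' instruction by that instruction's original boundary, leaving the
#' non-decision terms and the other instruction untouched. The rescaled
#' boundary becomes equal to the fixed scaling boundary, so the
#' baseline-to-boundary excursion no longer differs between instructions;
#' by the scaling property of sequential-sampling models the behavioral
#' predictions are unchanged (trial-for-trial identical in this
#' implementation, see [simulate_dataset()]), while the implied accumulator
#' trajectories are globally amplified.
#'
#' @param params A [race_params()] object (free-excursion form).
#' @param reference_cell Instruction whose cells are rescaled; default
#'   `"speed"`, the instruction whose boundary was left free.
#' @return A `race_params` object in forced-excursion form.
#' @examples
#' free <- sat_reference_params("tms")
#' forced <- to_forced_excursion(free)
#' # 0.523 / 0.893 = 0.586 to table precision
#' round(subset(forced$cells, instruction == "speed")$s_z[1], 3)
#' @export
to_forced_excursion <- function(params, reference_cell = "speed") {
  stopifnot(inherits(params, "race_params"))
  if (!reference_cell %in% .instructions)
    stop("`reference_cell` must be one of: ", paste(.instructions, collapse = ", "))
  rows <- params$cells$instruction == reference_cell
  a_ref <- unique(params$cells$a[rows])
  if (length(a_ref) != 1L)
    stop("cells of the reference instruction must share one boundary")
  if (a_ref <= 0) stop("reference boundary must be positive")
  out <- params
  for (col in c("a", "s_z", "v_correct", "v_incorrect", "sigma"))
    out$cells[[col]][rows] <- params$cells[[col]][rows] / a_ref
  out
}

#' Bundled reference parameter estimates
#'
#' Group-level free-excursion estimates of the winning model variant
#' (boundary and start-point range free across instructions, drift rates
#' free across difficulty) for two variants of a random-dot-motion
#' experiment under speed/accuracy instructions: a TMS study analyzed in
#' median-normalized time and an EEG study analyzed in seconds. They are
#' the package's realistic defaults for simulation studies and worked
#' examples.
#'
#' @param study `"tms"` (times as proportions of median RT) or `"eeg"`
#'   (times in seconds).
#' @return A [race_params()] object in free-excursion form.
#' @examples
#' sat_reference_params("tms")
#' @export
sat_reference_params <- function(study = c("tms", "eeg")) {
  study <- match.arg(study)
  if (study == "tms") {
    race_params(a = c(accuracy = 1, speed = 0.893),
                s_z = c(accuracy = 0.447, speed = 0.523),
                v_correct = c(easy = 1.280, hard = 0.634),
                v_incorrect = c(easy = 0.098, hard = 0.004),
                sigma = 0.499, t_er = 0.382, s_ter = 0.374,
                unit = "prop_median_rt")
  } else {
    race_params(a = c(accuracy = 1, speed = 0.815),
                s_z = c(accuracy = 0.319, speed = 0.541),
                v_correct = c(easy = 2.475, hard = 1.350),
                v_incorrect = c(easy = 0.253, hard = 0.054),
                sigma = 0.785, t_er = 0.257, s_ter = 0.229,
                unit = "s")
  }
}

#' Write / read a parameter set as structured JSON
#'
#' The layout mirrors the per-cell table plus global non-decision terms,
#' so files are human-readable and diffable.
#'
#' @param params A [race_params()] object.
#' @param path File path.
#' @return `read_params()` returns a `race_params` object;
#'   `write_params()` returns `path` invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "race_params"))
  obj <- list(cells = params$cells,
              t_er = as.list(params$t_er), s_ter = params$s_ter,
              scaling_reference = params$scaling_reference, unit = params$unit)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  race_params(cells = obj$cells, t_er = unlist(obj$t_er), s_ter = obj$s_ter,
              scaling_reference = obj$scaling_reference, unit = obj$unit)
}
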