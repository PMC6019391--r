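#' Differential-evolution minimizer
#'
#' A classic rand-to-best/1/bin differential-evolution scheme with dithered
#' mutation factor, used as the global stage of the fitting pipeline. The
#' objective may be noisy-but-frozen (deterministic given its own seed),
#' which is how the quantile-based fitting objective is set up.
#'
#' @param fn Objective `function(par) -> scalar` to minimize; may return
#'   `Inf` for infeasible points.
#' @param lower,upper Numeric bounds (same length); the population is
#'   initialized uniformly inside the box and proposals are reflected back
#'   into it.
#' @param control List: `pop` (population size, default `10 * d` capped at
#'   40), `iter` generations (default 100), `cr` crossover rate (0.9),
#'   `f` base mutation factor (0.8, dithered by +/-0.2), `seed` (1),
#'   `init` optional matrix of initial members (rows), `tol` early-stop
#'   spread (default 1e-8), `trace` record best value per generation.
#' @return List with `par`, `value`, `trace` (best objective per
#'   generation), `evals`.
#' @export
de_optimize <- function(fn, lower, upper, control = list()) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper >= lower))
  ctl <- modifyList(list(pop = min(10L * d, 40L), iter = 100L, cr = 0.9,
                         f = 0.8, seed = 1L, init = NULL, tol = 1e-8,
                         trace = TRUE), control)
  np <- max(ctl$pop, 5L)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(ctl$seed)
  pop <- matrix(runif(np * d, rep(lower, each = np), rep(upper, each = np)),
                nrow = np)
  if (!is.null(ctl$init)) {
    ini <- rbind(ctl$init)
    k <- min(nrow(ini), np)
    pop[seq_len(k), ] <- pmin(pmax(ini[seq_len(k), , drop = FALSE],
                                   rep(lower, each = k)), rep(upper, each = k))
  }
  val <- apply(pop, 1, fn)
  evals <- np
  trace <- numeric(0)
  for (g in seq_len(ctl$iter)) {
    b <- which.min(val)
    for (i in seq_len(np)) {
      idx <- sample.int(np, 2L)
      fg <- ctl$f + runif(1, -0.2, 0.2)
      cand <- pop[i, ] + fg * (pop[b, ] - pop[i, ]) +
        fg * (pop[idx[1], ] - pop[idx[2], ])
      keep <- runif(d) > ctl$cr
      keep[sample.int(d, 1L)] <- FALSE
      cand[keep] <- pop[i, keep]
      # reflect out-of-box proposals back inside
      below <- cand < lower; cand[below] <- pmin(2 * lower[below] - cand[below], upper[below])
      above <- cand > upper; cand[above] <- pmax(2 * upper[above] - cand[above], lower[above])
      cand <- pmin(pmax(cand, lower), upper)
      cv <- fn(cand)
      evals <- evals + 1L
      if (cv <= val[i]) { pop[i, ] <- cand; val[i] <- cv }
    }
    if (ctl$trace) trace <- c(trace, min(val))
    if (diff(range(val[is.finite(val)])) < ctl$tol) break
  }
  b <- which.min(val)
  list(par = pop[b, ], value = val[b], trace = trace, evals = evals)
}
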