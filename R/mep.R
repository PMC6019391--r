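#' Standardize MEP amplitudes within recording groups
#'
#' Z-transforms amplitudes separately within each grouping cell (by default
#' muscle role x participant x session), the normalization applied before
#' pooling trials across participants. Optionally divides stimulation
#' latencies by a per-session median reaction time so that all latencies
#' live on the proportion-of-median-RT scale.
#'
#' @param records Data frame of MEP records with at least the grouping
#'   columns and `amplitude`; usually also `trial_id` and `tms_latency`.
#' @param by Character vector of grouping columns.
#' @param median_rt Optional: a single value, or a named vector indexed by
#'   `session`, used to divide `tms_latency`.
#' @return `records` with an added `amplitude_z` column (and rescaled
#'   `tms_latency` if requested). Groups with fewer than 2 records or zero
#'   amplitude variance are dropped with a warning.
#' @export
zscore_amplitudes <- function(records,
                              by = c("muscle_role", "participant_id", "session"),
                              median_rt = NULL) {
  if (!all(by %in% names(records))) stop("missing grouping columns: ",
                                         paste(setdiff(by, names(records)), collapse = ", "))
  if (!"amplitude" %in% names(records)) stop("`records` needs an `amplitude` column")
  g <- interaction(records[by], drop = TRUE)
  z <- rep(NA_real_, nrow(records))
  dropped <- character(0)
  for (lev in levels(g)) {
    sel <- g == lev
    a <- records$amplitude[sel]
    if (length(a) < 2L || sd(a) == 0) { dropped <- c(dropped, lev); next }
    z[sel] <- (a - mean(a)) / sd(a)
  }
  if (length(dropped)) {
    warning("dropping ", length(dropped),
            " group(s) with <2 records or zero variance: ",
            paste(utils::head(dropped, 5), collapse = ", "))
    keep <- !is.na(z)
    records <- records[keep, , drop = FALSE]
    z <- z[keep]
  }
  records$amplitude_z <- z
  if (!is.null(median_rt)) {
    m <- if (is.null(names(median_rt))) rep(median_rt, nrow(records))
         else unname(median_rt[as.character(records$session)])
    records$tms_latency <- records$tms_latency / m
  }
  records
}

#' Responding-minus-nonresponding MEP differences
#'
#' Collapses the paired records of each stimulated trial into one point:
#' the standardized amplitude of the responding muscle minus that of the
#' nonresponding muscle, at the shared stimulation latency. The difference
#' removes nonspecific influences (e.g. global preparatory suppression)
#' that affect both muscles alike.
#'
#' @param paired MEP record table with columns `trial_id`, `muscle_role`
#'   (`"responding"` / `"nonresponding"`), `tms_latency`, `amplitude_z`.
#' @return Data frame with one row per trial: `trial_id`, `t` (latency),
#'   `y` (difference), plus `instruction` / `difficulty` / `rt` columns
#'   when present in the input.
#' @export
difference_records <- function(paired) {
  need <- c("trial_id", "muscle_role", "tms_latency", "amplitude_z")
  if (!all(need %in% names(paired))) stop("missing columns: ",
                                          paste(setdiff(need, names(paired)), collapse = ", "))
  sp <- split(paired, paired$trial_id)
  rows <- lapply(sp, function(d) {
    r <- d[d$muscle_role == "responding", ]
    n <- d[d$muscle_role == "nonresponding", ]
    if (nrow(r) != 1L || nrow(n) != 1L)
      stop("trial ", d$trial_id[1], " is not a responding/nonresponding pair")
    if (abs(r$tms_latency - n$tms_latency) > 1e-9)
      stop("trial ", d$trial_id[1], " has mismatched latencies across muscles")
    out <- data.frame(trial_id = r$trial_id, t = r$tms_latency,
                      y = r$amplitude_z - n$amplitude_z,
                      stringsAsFactors = FALSE)
    for (col in c("instruction", "difficulty", "rt", "participant_id", "session"))
      if (col %in% names(r)) out[[col]] <- r[[col]]
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

# ---- BCa machinery ---------------------------------------------------------

# Shared BCa arithmetic: given observed statistic vector, a (stat x B) boot
# matrix and a (stat x N) jackknife matrix (or NULL for plain BC), return
# lower/upper bounds at `level`.
.bca_bounds <- function(obs, boot, jack, level) {
  B <- ncol(boot)
  p_low <- (1 - level) / 2
  z_lo <- qnorm(p_low); z_hi <- qnorm(1 - p_low)
  lo <- hi <- numeric(length(obs))
  for (gpt in seq_along(obs)) {
    bg <- boot[gpt, ]
    bg <- bg[is.finite(bg)]
    if (length(bg) == 0L || is.na(obs[gpt])) { lo[gpt] <- hi[gpt] <- NA_real_; next }
    if (max(bg) - min(bg) == 0) { lo[gpt] <- hi[gpt] <- bg[1]; next }
    z0 <- qnorm(.clamp(mean(bg < obs[gpt]) + 0.5 * mean(bg == obs[gpt]),
                       1 / (length(bg) + 1), length(bg) / (length(bg) + 1)))
    a <- 0
    if (!is.null(jack)) {
      th <- jack[gpt, ]
      th <- th[is.finite(th)]
      d <- mean(th) - th
      denom <- sum(d^2)^1.5
      if (denom > 0) a <- sum(d^3) / (6 * denom)
    }
    a1 <- pnorm(z0 + (z0 + z_lo) / (1 - a * (z0 + z_lo)))
    a2 <- pnorm(z0 + (z0 + z_hi) / (1 - a * (z0 + z_hi)))
    q <- quantile(bg, .clamp(c(a1, a2), 0, 1), type = 7, names = FALSE)
    lo[gpt] <- q[1]; hi[gpt] <- q[2]
  }
  list(lower = lo, upper = hi)
}

#' Bias-corrected (and accelerated) bootstrap confidence interval
#'
#' Resamples observations with replacement, recomputes a statistic (which
#' may be vector-valued, e.g. a whole smoothed signal) and returns BCa
#' bounds: the bias correction `z0` comes from the proportion of bootstrap
#' values below the observed value, the acceleration from jackknife
#' skewness. With `accelerated = FALSE` the acceleration is set to zero
#' (the plain bias-corrected variant, cheaper because no jackknife pass is
#' needed).
#'
#' @param data Vector or data frame of observations (rows are resampled).
#' @param statistic `function(data) -> numeric vector`.
#' @param n_boot Number of bootstrap resamples (>= 199).
#' @param level Coverage level (default 0.95).
#' @param accelerated Include the acceleration term (default `TRUE`).
#' @param seed Seed for the resampling.
#' @param indices Optional precomputed `n x n_boot` matrix of resample row
#'   indices (overrides `seed`), for exact cross-checks.
#' @return List with `observed`, `lower`, `upper`, `boot` (the bootstrap
#'   statistic matrix, statistics in rows).
#' @export
bca_interval <- function(data, statistic, n_boot = 1999, level = 0.95,
                         accelerated = TRUE, seed = 1, indices = NULL) {
  if (is.null(indices) && n_boot < 199) stop("`n_boot` must be at least 199")
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  take <- if (is.data.frame(data)) function(i) data[i, , drop = FALSE]
          else function(i) data[i]
  obs <- statistic(data)
  if (is.null(indices))
    indices <- .with_seed(seed,
      matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n))
  boot <- vapply(seq_len(ncol(indices)),
                 function(b) statistic(take(indices[, b])),
                 numeric(length(obs)))
  boot <- matrix(boot, nrow = length(obs))
  jack <- NULL
  if (accelerated) {
    jack <- vapply(seq_len(n), function(i) statistic(take(-i)),
                   numeric(length(obs)))
    jack <- matrix(jack, nrow = length(obs))
  }
  deg <- apply(boot, 1, function(r) max(r) - min(r) == 0)
  if (any(deg, na.rm = TRUE))
    warning("degenerate bootstrap distribution at ", sum(deg),
            " point(s); returning point interval there")
  b <- .bca_bounds(obs, boot, jack, level)
  list(observed = obs, lower = b$lower, upper = b$upper, boot = boot)
}

# Fast BCa band for a Gaussian-kernel-smoothed signal: the bootstrap and
# jackknife signals are linear-algebra expressions in the fixed weight
# matrix, so no per-resample smoothing loop is needed.  Mirrors
# bca_interval(statistic = smoothed signal) exactly.
.smooth_bca_band <- function(t, y, grid, fwhm, n_boot, level,
                             accelerated = TRUE, seed = 1, min_weight = 1,
                             counts = NULL) {
  n <- length(t)
  sk <- fwhm / (2 * sqrt(2 * log(2)))
  W <- exp(-outer(grid, t, "-")^2 / (2 * sk^2))
  sw <- rowSums(W)
  obs <- as.vector(W %*% y) / sw
  mask <- sw < min_weight
  obs[mask] <- NA_real_
  if (is.null(counts))
    counts <- .with_seed(seed, {
      idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
      apply(idx, 2, tabulate, nbins = n)
    })
  boot <- (W %*% (counts * y)) / (W %*% counts)
  jack <- NULL
  if (accelerated) {
    num <- as.vector(W %*% y)
    jack <- (num - W * rep(y, each = length(grid))) / (sw - W)
  }
  b <- .bca_bounds(obs, boot, jack, level)
  b$lower[mask] <- NA_real_; b$upper[mask] <- NA_real_
  race_signal(grid, obs, n_eff = sw, alignment = "stimulus", unit = "",
              ci_low = b$lower, ci_high = b$upper)
}

#' Smoothed signal with bootstrap confidence band
#'
#' Convenience wrapper producing the kernel-smoothed signal of a set of
#' (time, amplitude) points together with its per-grid-point BCa (or plain
#' bias-corrected) bootstrap band, resampling trials with replacement.
#'
#' @inheritParams kernel_smooth
#' @param n_boot,level,accelerated,seed As [bca_interval()].
#' @return A [race_signal()] with `ci_low` / `ci_high` columns.
#' @export
mep_signal <- function(t, y, grid, fwhm, n_boot = 1999, level = 0.95,
                       accelerated = TRUE, seed = 1, min_weight = 1,
                       alignment = "stimulus", unit = "s") {
  out <- .smooth_bca_band(t, y, grid, fwhm, n_boot, level, accelerated,
                          seed, min_weight)
  attr(out, "alignment") <- alignment
  attr(out, "unit") <- unit
  out
}

# ---- permutation tests -----------------------------------------------------

.perm_p <- function(null, observed) {
  # two-sided exact-test convention with +1 correction, doubled and capped
  hi <- (1 + sum(null >= observed)) / (1 + length(null))
  lo <- (1 + sum(null <= observed)) / (1 + length(null))
  min(1, 2 * min(hi, lo))
}

#' Permutation test on smoothed-signal build-up slopes
#'
#' Compares the build-up slope of two groups' smoothed signals by permuting
#' group labels across trials: per permutation the two signals are
#' recomputed from the relabelled points and the slope difference over the
#' analysis window re-estimated. Significance follows the percentile rule
#' (observed difference beyond the null's central 95%); the reported
#' p-value uses the add-one permutation convention, two-sided.
#'
#' @param records_a,records_b Data frames with columns `t` and `y` (e.g.
#'   from [difference_records()]).
#' @param window Slope window `(t_start, t_end)`.
#' @param grid Smoothing grid spanning at least the window.
#' @param fwhm Kernel width, as [kernel_smooth()].
#' @param n_perm Number of permutations (>= 99).
#' @param seed RNG seed.
#' @return List: `observed` slope difference (a minus b), `p`, per-group
#'   slopes, and the permutation null distribution.
#' @export
permutation_slope_test <- function(records_a, records_b, window, grid, fwhm,
                                   n_perm = 1999, seed = 1) {
  if (n_perm < 99) stop("`n_perm` must be at least 99")
  if (nrow(records_a) == 0L || nrow(records_b) == 0L)
    stop("both groups must be non-empty")
  t_all <- c(records_a$t, records_b$t)
  y_all <- c(records_a$y, records_b$y)
  n_a <- nrow(records_a); n <- length(t_all)
  gsel <- grid >= window[1] - 1e-9 & grid <= window[2] + 1e-9
  if (sum(gsel) < 3L) stop("need at least 3 grid points inside the window")
  gw <- grid[gsel]
  sk <- fwhm / (2 * sqrt(2 * log(2)))
  W <- exp(-outer(gw, t_all, "-")^2 / (2 * sk^2))
  xc <- gw - mean(gw)
  slope_of <- function(v) as.vector(crossprod(xc, v)) / sum(xc^2)
  sig <- function(member) {  # member: logical n-vector or 0/1 matrix n x B
    num <- W %*% (member * y_all)
    den <- W %*% member
    num / den
  }
  m_obs <- cbind(as.numeric(seq_len(n) <= n_a))
  s_a <- slope_of(sig(m_obs))
  s_b <- slope_of(sig(1 - m_obs))
  observed <- s_a - s_b
  perm <- .with_seed(seed,
    vapply(seq_len(n_perm), function(b) sample.int(n, n_a), integer(n_a)))
  M <- matrix(0, n, n_perm)
  M[cbind(as.vector(perm), rep(seq_len(n_perm), each = n_a))] <- 1
  null <- slope_of(sig(M)) - slope_of(sig(1 - M))
  list(observed = observed, p = .perm_p(null, observed),
       slope_a = s_a, slope_b = s_b, null = null)
}

.find_clusters <- function(flag) {
  # maximal runs of TRUE; returns start/end index pairs
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

.cluster_stats <- function(t_all, y_all, member, grid, fwhm, n_boot, level,
                           seed, min_weight) {
  a <- .smooth_bca_band(t_all[member], y_all[member], grid, fwhm, n_boot,
                        level, accelerated = TRUE, seed = seed,
                        min_weight = min_weight)
  b <- .smooth_bca_band(t_all[!member], y_all[!member], grid, fwhm, n_boot,
                        level, accelerated = TRUE, seed = seed + 1,
                        min_weight = min_weight)
  apart <- (a$ci_low > b$ci_high) | (b$ci_low > a$ci_high)
  cl <- .find_clusters(apart)
  diffs <- a$value - b$value
  sums <- if (nrow(cl) == 0L) numeric(0)
          else apply(cl, 1, function(r) sum(diffs[r[1]:r[2]]))
  list(clusters = cl, sums = sums, signal_a = a, signal_b = b)
}

#' Cluster-based permutation test on signal amplitudes
#'
#' Controls the family-wise error of point-by-point amplitude comparisons
#' between two groups of (time, amplitude) points. Candidate clusters are
#' maximal runs of grid points where the two groups' bootstrap BCa bands
#' (at `cluster_level`, the cluster-forming threshold) do not overlap; each
#' cluster's statistic is the sum of point-wise differences. Significance
#' is assessed against the permutation distribution of the largest
#' absolute cluster sum, obtained by relabelling trials and re-running the
#' identical band-and-cluster construction.
#'
#' @inheritParams permutation_slope_test
#' @param n_boot Bootstrap resamples per confidence band.
#' @param cluster_level Level of the cluster-forming band (default 0.90).
#' @param min_weight Masking threshold for sparse grid points.
#' @return A data frame of clusters (`onset`, `offset`, `sum`, `p`), sorted
#'   by onset (zero rows when no candidate cluster exists), with the two
#'   banded signals and the null distribution as attributes.
#' @export
cluster_amplitude_test <- function(records_a, records_b, grid, fwhm,
                                   n_boot = 1999, cluster_level = 0.90,
                                   n_perm = 1999, seed = 1, min_weight = 1) {
  if (n_perm < 99) stop("`n_perm` must be at least 99")
  t_all <- c(records_a$t, records_b$t)
  y_all <- c(records_a$y, records_b$y)
  n_a <- nrow(records_a); n <- length(t_all)
  obs <- .cluster_stats(t_all, y_all, seq_len(n) <= n_a, grid, fwhm, n_boot,
                        cluster_level, seed, min_weight)
  perm_idx <- .with_seed(seed,
    vapply(seq_len(n_perm), function(b) sample.int(n, n_a), integer(n_a)))
  null_max <- vapply(seq_len(n_perm), function(b) {
    member <- logical(n); member[perm_idx[, b]] <- TRUE
    st <- .cluster_stats(t_all, y_all, member, grid, fwhm, n_boot,
                         cluster_level, seed + 2 * b, min_weight)
    if (length(st$sums) == 0L) 0 else max(abs(st$sums))
  }, numeric(1))
  if (nrow(obs$clusters) > 0L) {
    p <- vapply(abs(obs$sums), function(s)
      (1 + sum(null_max >= s)) / (1 + n_perm), numeric(1))
    res <- data.frame(onset = grid[obs$clusters[, "start"]],
                      offset = grid[obs$clusters[, "end"]],
                      n_points = obs$clusters[, "end"] - obs$clusters[, "start"] + 1L,
                      sum = obs$sums, p = p)
    res <- res[order(res$onset), , drop = FALSE]
    rownames(res) <- NULL
  } else {
    res <- data.frame(onset = numeric(0), offset = numeric(0),
                      n_points = integer(0), sum = numeric(0), p = numeric(0))
  }
  attr(res, "signal_a") <- obs$signal_a
  attr(res, "signal_b") <- obs$signal_b
  attr(res, "null_max") <- null_max
  res
}

# ---- model-predicted MEP signals ------------------------------------------

#' Model-predicted smoothed MEP difference signals
#'
#' Generates the neurodynamic prediction of a parameter set for the
#' corticospinal read-out: single-trial accumulation paths are sampled at
#' simulated stimulation latencies (drawn from the supplied schedule), the
#' correct-minus-incorrect accumulator difference at the pulse is treated
#' as the modelled MEP difference, and the same Gaussian-kernel smoothing
#' applied to empirical MEPs produces stimulus- and response-locked
#' signals. Only correct trials enter, the whole non-decision time is
#' allocated to pre-accumulation delay (read-outs are 0 before
#' accumulation onset), and trials whose simulated response precedes the
#' pulse are discarded, mirroring pulse cancellation.
#'
#' @param params A [race_params()] object.
#' @param schedule Data frame of stimulation times with columns
#'   `instruction` and `latency` (stimulus-locked, same unit as `params`);
#'   typically delivered pulses from [generate_tms_schedule()] or an
#'   empirical schedule. Latencies are resampled with replacement per
#'   simulated trial within instruction.
#' @param sim A [sim_config()]; the emulated analyses used 20000 paths per
#'   condition at 0.5% median-RT steps.
#' @param scale Multiplicative amplitude factor applied to the difference
#'   values (fit via [fit_amplitude_scale()] when comparing to data).
#' @param fwhm Smoothing kernel width.
#' @param stim_grid,resp_grid Output grids (stimulus-locked, and
#'   response-locked with 0 = response).
#' @param min_weight Masking threshold for sparse grid points.
#' @return Named list of [race_signal()] objects, one per condition and
#'   alignment, names `instruction.difficulty.alignment`. Only instructions
#'   present in the schedule are predicted.
#' @export
predict_mep_signal <- function(params, schedule, sim = sim_config(dt = 0.005,
                                 n_trials = 20000),
                               scale = 1, fwhm = 0.05,
                               stim_grid = seq(0, 1.5, by = 0.01),
                               resp_grid = seq(-1, 0, by = 0.01),
                               min_weight = 1) {
  stopifnot(inherits(params, "race_params"))
  if (!all(c("instruction", "latency") %in% names(schedule)))
    stop("`schedule` needs columns `instruction` and `latency`")
  ms <- .max_steps(sim)
  out <- list()
  cells <- params$cells
  use <- which(cells$instruction %in% unique(schedule$instruction))
  if (length(use) == 0L)
    stop("no schedule latencies for any instruction in `params`")
  for (i in use) {
    instr <- cells$instruction[i]; diff <- cells$difficulty[i]
    lats <- schedule$latency[schedule$instruction == instr]
    q <- .with_seed(sim$seed + i, sample(lats, sim$n_trials, replace = TRUE))
    cond <- cell_params(params, instr, diff)
    z <- race_sample_cpp(sim$n_trials, cond$a, cond$s_z, cond$v_correct,
                         cond$v_incorrect, cond$sigma,
                         unname(params$t_er[instr]), params$s_ter,
                         sim$dt, ms, q, sim$seed, (i - 1) * sim$n_trials)
    rt <- z$steps * sim$dt + z$ndt
    keep <- z$choice == 1L & rt >= q  # correct trials surviving censoring
    d <- (z$x_correct - z$x_incorrect)[keep] * scale
    tq <- q[keep]; trt <- rt[keep]
    key <- paste(instr, diff, sep = ".")
    out[[paste0(key, ".stimulus")]] <-
      kernel_smooth(tq, d, stim_grid, fwhm, min_weight,
                    alignment = "stimulus", unit = params$unit)
    out[[paste0(key, ".response")]] <-
      kernel_smooth(tq - trt, d, resp_grid, fwhm, min_weight,
                    alignment = "response", unit = params$unit)
  }
  out
}
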