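#' Mean squared error between matched signal lists
#'
#' Pools the squared differences over all grid points that are unmasked in
#' both the prediction and the observation, across every signal pair that
#' the two lists share by name.
#'
#' @param pred,obs Named lists of [race_signal()]s (or two single
#'   signals); matching is by name.
#' @return Scalar mean squared error.
#' @export
signal_mse <- function(pred, obs) {
  pr <- .pair_signals(pred, obs)
  d2 <- unlist(lapply(pr, function(p) (p$p - p$o)^2))
  if (length(d2) == 0L) stop("no overlapping unmasked points")
  mean(d2)
}

#' Closed-form amplitude scale
#'
#' The multiplicative factor `c` minimizing the mean squared error between
#' `c * prediction` and observation over all shared unmasked points:
#' `c = sum(p * o) / sum(p^2)`.
#'
#' @inheritParams signal_mse
#' @return The least-squares scale factor.
#' @export
fit_amplitude_scale <- function(pred, obs) {
  pr <- .pair_signals(pred, obs)
  num <- sum(unlist(lapply(pr, function(p) p$p * p$o)))
  den <- sum(unlist(lapply(pr, function(p) p$p^2)))
  if (!is.finite(den) || den == 0) stop("prediction is identically zero; scale undefined")
  num / den
}

#' Apply an amplitude scale to a signal list
#'
#' @param pred Named list of [race_signal()]s (or one signal).
#' @param scale Multiplicative factor.
#' @return The scaled list.
#' @export
scale_signals <- function(pred, scale) {
  one <- function(s) { s$value <- s$value * scale; s }
  if (inherits(pred, "race_signal")) one(pred) else lapply(pred, one)
}

.pair_signals <- function(pred, obs) {
  if (inherits(pred, "race_signal")) pred <- list(signal = pred)
  if (inherits(obs, "race_signal")) obs <- list(signal = obs)
  nm <- intersect(names(pred), names(obs))
  if (length(nm) == 0L) stop("`pred` and `obs` share no signal names")
  lapply(nm, function(k) {
    p <- pred[[k]]; o <- obs[[k]]
    if (nrow(p) != nrow(o) || max(abs(p$time - o$time)) > 1e-8)
      stop("signal '", k, "' is on a different grid in `pred` and `obs`")
    use <- !is.na(p$value) & !is.na(o$value)
    list(p = p$value[use], o = o$value[use])
  })
}

#' AIC from a mean squared error
#'
#' Gaussian-error information criterion for curve fits scored by MSE:
#' `n * log(mse) + 2 * k`, with `k` the number of free signal-mapping
#' parameters (1 for an amplitude scale alone).
#'
#' @param mse Mean squared error.
#' @param n Number of points entering the MSE.
#' @param k Number of free mapping parameters.
#' @return The criterion value.
#' @export
aic_from_mse <- function(mse, n, k = 1) {
  if (mse <= 0) stop("`mse` must be positive")
  n * log(mse) + 2 * k
}

#' Bootstrap test of an MSE difference between two model variants
#'
#' Resamples behavioral trials with replacement, re-runs a user-supplied
#' pipeline (refit / re-express / predict / observe) on each replicate and
#' records the difference in neural MSE between two model variants. The
#' interval is bias-corrected (percentile interval shifted by the normal
#' quantile of the proportion of replicates below the observed
#' difference), and the p-value is obtained by interval inversion: the
#' smallest level `alpha` at which the bias-corrected
#' `(1 - alpha)` interval excludes zero.
#'
#' @param trials Behavioral trial table (rows are resampled).
#' @param neural Neural data object passed through to the pipeline.
#' @param pipeline List of functions:
#'   `statistic(trials, neural)` returning the scalar MSE difference for
#'   one (re)sampled data set. Replicates returning `NA` or erroring are
#'   dropped; more than 5% failures aborts.
#' @param n_boot Number of bootstrap replicates.
#' @param seed RNG seed for resampling.
#' @param level Interval level (default 0.95).
#' @return List with `observed`, `ci`, `p`, `boot`, `n_failed`.
#' @export
bootstrap_mse_difference <- function(trials, neural, pipeline,
                                     n_boot = 1999, seed = 1, level = 0.95) {
  if (!is.function(pipeline$statistic)) stop("pipeline$statistic must be a function")
  n <- nrow(trials)
  observed <- pipeline$statistic(trials, neural)
  boot <- .with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(pipeline$statistic(trials[idx, , drop = FALSE], neural),
               error = function(e) NA_real_)
    }, numeric(1))
  })
  n_failed <- sum(!is.finite(boot))
  if (n_failed > 0.05 * n_boot)
    stop("more than 5% of bootstrap replicates failed (", n_failed, "/", n_boot, ")")
  bg <- boot[is.finite(boot)]
  ci <- .bc_ci(observed, bg, level)
  list(observed = observed, ci = ci, p = .bc_invert_p(observed, bg),
       boot = boot, n_failed = n_failed)
}

# Bias-corrected percentile interval (acceleration 0).
.bc_ci <- function(obs, bg, level) {
  B <- length(bg)
  prop <- (sum(bg < obs) + 0.5 * sum(bg == obs)) / B
  prop <- .clamp(prop, 1 / (B + 1), B / (B + 1))
  z0 <- qnorm(prop)
  al <- (1 - level) / 2
  a1 <- pnorm(2 * z0 + qnorm(al))
  a2 <- pnorm(2 * z0 + qnorm(1 - al))
  unname(quantile(bg, c(a1, a2), type = 7, names = FALSE))
}

# Smallest alpha whose (1 - alpha) bias-corrected interval excludes zero.
.bc_invert_p <- function(obs, bg, tol = 1e-5) {
  excl <- function(alpha) {
    ci <- .bc_ci(obs, bg, 1 - alpha)
    ci[1] > 0 || ci[2] < 0
  }
  if (!excl(1 - 1e-9)) return(1)          # even near-zero-width interval covers 0
  if (excl(tol)) return(tol)
  lo <- tol; hi <- 1 - 1e-9               # excl(hi) TRUE, excl(lo) FALSE
  # excl is monotone non-decreasing in alpha; bisect for the boundary
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (excl(mid)) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  hi
}
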