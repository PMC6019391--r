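test_that("type-7 quantiles reproduce the textbook interpolation", {
  expect_equal(empirical_quantiles(1:11), c(2, 4, 6, 8, 10))
  expect_equal(empirical_quantiles(c(3, 1, 2), probs = 0.5), 2)
  expect_error(empirical_quantiles(1), "at least 2")
  expect_error(empirical_quantiles(1:10, probs = c(0.5, 0.3)), "increasing")
})

test_that("bin counts partition observations by quantile edges", {
  edges <- c(2, 4, 6, 8, 10)
  expect_equal(raceSAT:::.bin_counts(1:11, edges),
               c(1, 2, 2, 2, 2, 2))
  expect_equal(sum(raceSAT:::.bin_counts(runif(57, 0, 20), edges)), 57)
  expect_equal(raceSAT:::.bin_counts(c(1, 2, 3), NULL), 3)  # single bin
})

test_that("quantile schemes collapse sparse error cells", {
  mk <- function(n_err) {
    rbind(data.frame(instruction = rep(c("accuracy", "speed"), each = 2),
                     difficulty = rep(c("easy", "hard"), 2))[rep(1:4, each = 40), ],
          data.frame(instruction = "accuracy", difficulty = "easy")[rep(1, n_err), , drop = FALSE]) |>
      within({
        choice <- "correct"
        rt <- seq(0.4, 2, length.out = 160 + n_err)
      })
  }
  d <- mk(0)
  d$choice[1:25] <- "incorrect"             # accuracy/easy gets 25 errors
  d$choice[41:43] <- "incorrect"            # accuracy/hard gets 3 errors
  s <- quantile_scheme(d)
  cell_ae <- s$cells[[which(vapply(s$cells, function(c)
    c$instruction == "accuracy" && c$difficulty == "easy", TRUE))]]
  cell_ah <- s$cells[[which(vapply(s$cells, function(c)
    c$instruction == "accuracy" && c$difficulty == "hard", TRUE))]]
  cell_se <- s$cells[[which(vapply(s$cells, function(c)
    c$instruction == "speed" && c$difficulty == "easy", TRUE))]]
  expect_length(cell_ae$incorrect$edges, 5)   # full quantile set
  expect_length(cell_ah$incorrect$edges, 1)   # median-only collapse
  expect_null(cell_se$incorrect$edges)        # no errors: single mass bin
  expect_equal(sum(cell_ae$correct$counts) + sum(cell_ae$incorrect$counts),
               cell_ae$n_resp)
})

test_that("the quantile-bin likelihood matches a direct computation", {
  counts <- c(3, 7, 5)
  props <- c(0.2, 0.5, 0.3)
  expect_equal(qmpe_loglik(counts, props),
               3 * log(0.2) + 7 * log(0.5) + 5 * log(0.3))
  # zero proportions are floored, not -Inf
  expect_true(is.finite(qmpe_loglik(c(1, 1), c(0, 1))))
  expect_equal(qmpe_loglik(c(1, 0), c(0, 1)), log(1e-10))
  expect_error(qmpe_loglik(1:3, 1:2), "same length")
})

test_that("simulated bin masses reproduce the nominal quantile masses", {
  # Bins built from one sample's quantiles must catch the nominal masses
  # when the model evaluates the same generating parameters.
  p <- quick_params()
  dat <- simulate_dataset(p, four_cell_design(4000),
                          sim_config(n_trials = 4000, seed = 21))
  dat <- dat[dat$choice != "none", ]
  scheme <- quantile_scheme(dat)
  sim <- sim_config(n_trials = 20000, seed = 22)
  cell <- scheme$cells[[1]]
  cond <- cell_params(p, cell$instruction, cell$difficulty)
  z <- raceSAT:::race_sim_cpp(20000, cond$a, cond$s_z, cond$v_correct, cond$v_incorrect,
                    cond$sigma, 0.35, 0.3, 0.01, 500, 22L, 0L)
  rt <- z$steps * 0.01 + z$ndt
  props <- raceSAT:::.bin_counts(rt[z$choice == 1L], cell$correct$edges) /
    sum(z$choice != 0L)
  p_corr <- sum(cell$correct$counts) / cell$n_resp
  nominal <- p_corr * c(0.1, 0.2, 0.2, 0.2, 0.2, 0.1)
  expect_lt(max(abs(props - nominal)), 0.02)
})

test_that("information criteria follow their definitions", {
  ic <- information_criteria(-100, k = 10, n = 500)
  expect_equal(unname(ic["aic"]), 220)
  expect_equal(unname(ic["bic"]), 200 + 10 * log(500))
  # BIC - AIC = k (log n - 2) identically
  expect_equal(unname(ic["bic"] - ic["aic"]), 10 * (log(500) - 2))
})

test_that("Akaike weights match the closed form and resist overflow", {
  w <- akaike_weights(c(0, 2))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)))
  expect_equal(round(w, 4), c(0.7311, 0.2689))
  w2 <- akaike_weights(c(1e6, 1e6 + 2, 1e6 + 1000))
  expect_equal(sum(w2), 1)
  expect_false(any(is.nan(w2)))
  expect_gt(w2[1], w2[2])
  expect_equal(w2[3], 0)
})

test_that("the fitting objective is deterministic given its seed", {
  p <- quick_params()
  dat <- simulate_dataset(p, four_cell_design(1000),
                          sim_config(n_trials = 1000, seed = 3))
  dat <- dat[dat$choice != "none", ]
  scheme <- quantile_scheme(dat)
  sim <- sim_config(n_trials = 2000, seed = 17)
  expect_identical(evaluate_model(p, scheme, sim),
                   evaluate_model(p, scheme, sim))
})

test_that("theta packing and unpacking are mutually inverse", {
  for (name in c("model1", "model2", "model3")) {
    spec <- model_spec(name)
    p <- quick_params()
    if (name != "model2") {  # variants share the start-point range
      p$cells$s_z <- 0.4
    }
    th <- raceSAT:::.params_to_theta(p, spec)
    q <- raceSAT:::.theta_to_params(th, spec, unit = "s")
    expect_equal(q$cells$a, p$cells$a)
    expect_equal(q$cells$v_correct, p$cells$v_correct)
    expect_equal(q$cells$v_incorrect, p$cells$v_incorrect)
    expect_equal(q$t_er, p$t_er)
    expect_equal(q$s_ter, p$s_ter, tolerance = 1e-8)
  }
})

test_that("infeasible start-point ranges are rejected by the objective", {
  spec <- model_spec("model2")
  lay <- raceSAT:::.theta_layout(spec, 1)
  th <- raceSAT:::.params_to_theta(quick_params(), spec)
  th["s_z_speed"] <- 0.95 * th["a_speed"]  # s_z >= 0.95 a is infeasible
  expect_null(raceSAT:::.theta_to_params(th, spec, "s"))
})

test_that("model variants declare the documented parameter counts", {
  expect_equal(model_spec("model1")$n_free_parameters, 9L)
  expect_equal(model_spec("model2")$n_free_parameters, 10L)
  expect_equal(model_spec("model3")$n_free_parameters, 10L)
  expect_identical(model_spec("model2")$free_across_instructions, c("a", "s_z"))
})

test_that("a reduced-budget fit moves towards the generating parameters", {
  p <- quick_params()
  dat <- simulate_dataset(p, four_cell_design(2000),
                          sim_config(n_trials = 2000, seed = 61))
  dat <- dat[dat$choice != "none", ]
  ctl <- fit_control(n_sim = 2000, n_sim_de = 1000, dt_de = 0.02,
                     de = list(pop = 16, iter = 25), nm_maxit = 80, seed = 8)
  ft <- fit_model(dat, model_spec("model2"), ctl)
  expect_s3_class(ft, "race_fit")
  expect_true(is.finite(ft$log_likelihood))
  expect_equal(ft$k, 10L)
  expect_equal(ft$n_obs, nrow(dat))
  # the fit must beat a deliberately bad parameter set
  scheme <- quantile_scheme(dat)
  bad <- race_params(a = 1, s_z = 0.1, v_correct = 3, v_incorrect = 1,
                     sigma = 1, t_er = 0.1, s_ter = 0.1)
  sim <- sim_config(n_trials = 2000, seed = 8)
  expect_gt(ft$log_likelihood, evaluate_model(bad, scheme, sim))
  # deterministic under an identical control
  ft2 <- fit_model(dat, model_spec("model2"), ctl)
  expect_identical(ft$theta, ft2$theta)
})

test_that("simplex refinement never falls below its starting objective", {
  p <- quick_params()
  dat <- simulate_dataset(p, four_cell_design(1500),
                          sim_config(n_trials = 1500, seed = 62))
  dat <- dat[dat$choice != "none", ]
  ctl <- fit_control(n_sim = 1500, nm_maxit = 60, seed = 9)
  ft <- refit_simplex(dat, p, model_spec("model2"), ctl)
  scheme <- quantile_scheme(dat)
  ll_start <- evaluate_model(p, scheme,
                             sim_config(n_trials = 1500, seed = 9))
  expect_gte(ft$log_likelihood, ll_start - 1e-9)
})

test_that("fits refuse data with missing or underpopulated cells", {
  p <- quick_params()
  dat <- simulate_dataset(p, four_cell_design(500),
                          sim_config(n_trials = 500, seed = 1))
  expect_error(fit_model(dat[dat$instruction == "speed", ]), "correct trials")
})
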