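test_that("non-decision splits validate their components", {
  sp <- nondecision_split(0.2, 0.1)
  expect_equal(sp$t_e + sp$t_r, 0.3)
  expect_error(nondecision_split(-0.1, 0.2), ">= 0")
  p <- quick_params()  # t_er = 0.35
  expect_error(predict_cpp_traces(p, nondecision_split(0.1, 0.1),
                                  sim_config(n_trials = 10, seed = 1)),
               "must equal t_er")
})

test_that("noiseless summed traces ramp at the summed drift and peak at the motor response", {
  # deterministic ramp: v_c = 2, v_i = 0.5, crossing value 1, t_e = 0.2, t_r = 0.1
  p <- ramp_params(v = 2, vi = 0.5)  # t_er = 0.3, s_ter = 0
  sp <- nondecision_split(0.2, 0.1)
  ep <- predict_cpp_traces(p, sp, sim = sim_config(dt = 0.01, n_trials = 3,
                                                   seed = 1),
                           design = data.frame(instruction = "accuracy",
                                               difficulty = "easy"),
                           grid = seq(0, 1.2, 0.01))
  # crossing at 0.5 after onset; rt = 0.2 + 0.5 + 0.1 = 0.8
  expect_equal(ep$trials$rt, rep(0.8, 3), tolerance = 1e-9)
  expect_true(all(ep$trials$choice == "correct"))
  tr <- ep$amplitude[1, ]
  tt <- ep$times
  expect_equal(tr[tt <= 0.2 + 1e-9], rep(0, sum(tt <= 0.2 + 1e-9)),
               tolerance = 1e-9)
  # during accumulation the summed trace ramps at v_c + v_i
  mid <- tt > 0.25 & tt < 0.65
  slopes <- diff(tr[mid]) / 0.01
  expect_equal(slopes, rep(2.5, sum(mid) - 1), tolerance = 1e-6)
  # value at the response: crossing value + v_c * t_r + v_i * (t_cross + t_r)
  at_resp <- tr[which.min(abs(tt - 0.8))]
  expect_equal(at_resp, (1 + 2 * 0.1) + 0.5 * (0.5 + 0.1), tolerance = 1e-6)
  # masked after the response
  expect_true(all(is.na(tr[tt > 0.8 + 1e-9])))
})

test_that("trace simulation reproduces the behavioral reaction times exactly", {
  p <- quick_params()
  des <- four_cell_design(400)
  sim <- sim_config(dt = 0.01, n_trials = 400, seed = 44)
  beh <- simulate_dataset(p, des, sim)
  sp <- nondecision_split(0.25, 0.1)  # 0.25 + 0.1 = t_er = 0.35
  ep <- predict_cpp_traces(p, sp, sim = sim,
                           design = four_cell_design(400))
  resp <- beh$choice != "none"
  expect_equal(ep$trials$rt[resp], beh$rt[resp], tolerance = 1e-12)
  expect_identical(ep$trials$choice, beh$choice)
})

test_that("baseline correction zeroes the first sample of every trial", {
  ep <- epoch_set(c(0, 0.1, 0.2), rbind(c(1, 2, 3), c(-1, 0, NA)),
                  data.frame(rt = c(0.2, 0.1)))
  bc <- baseline_correct(ep)
  expect_equal(bc$amplitude[, 1], c(0, 0))
  expect_equal(bc$amplitude[1, ], c(0, 1, 2))
  expect_true(is.na(bc$amplitude[2, 3]))
})

test_that("censored averaging matches a hand-computed two-trial example", {
  times <- seq(0, 0.4, 0.1)
  amp <- rbind(c(0, 1, 2, 3, NA),   # rt 0.3
               c(0, 2, 4, 6, 8))    # rt 0.5
  ep <- epoch_set(times, amp,
                  data.frame(rt = c(0.3, 0.5),
                             choice = c("correct", "correct")))
  st <- censored_average(ep, "stimulus")
  # t < 0.3: both trials; 0.3 <= t < 0.5: only trial 2
  expect_equal(st$value, c(0, 1.5, 3, 6, 8))
  expect_equal(st$n_eff, c(2, 2, 2, 1, 1))
  re <- censored_average(ep, "response", resp_grid = seq(-0.3, 0, 0.1))
  # response-aligned: trial 1 contributes samples at rt 0.3 (index 4),
  # trial 2 has rt 0.5 beyond the grid, so alignment clips to sample 5
  expect_s3_class(re, "race_signal")
  expect_equal(attr(re, "alignment"), "response")
})

test_that("response-locked averages align trials at their response sample", {
  times <- seq(0, 0.4, 0.1)
  amp <- rbind(c(10, 11, 12, NA, NA),  # rt 0.2 -> response sample index 3
               c(20, 21, 22, 23, NA))  # rt 0.3 -> response sample index 4
  ep <- epoch_set(times, amp, data.frame(rt = c(0.2, 0.3),
                                         choice = c("correct", "correct")))
  re <- censored_average(ep, "response", resp_grid = seq(-0.2, 0, 0.1))
  expect_equal(re$value, c((10 + 21) / 2, (11 + 22) / 2, (12 + 23) / 2))
  expect_equal(re$n_eff, c(2, 2, 2))
})

test_that("only requested choices enter the average", {
  times <- c(0, 0.1)
  amp <- rbind(c(1, 1), c(100, 100))
  ep <- epoch_set(times, amp, data.frame(rt = c(0.5, 0.5),
                                         choice = c("correct", "incorrect")))
  st <- censored_average(ep, "stimulus")
  expect_equal(st$value, c(1, 1))
  both <- censored_average(ep, "stimulus", choices = c("correct", "incorrect"))
  expect_equal(both$value, c(50.5, 50.5))
})

test_that("condition averages are keyed by cell and alignment", {
  p <- quick_params()
  sp <- nondecision_split(0.25, 0.1)
  ep <- predict_cpp_traces(p, sp, sim = sim_config(dt = 0.01, n_trials = 150,
                                                   seed = 3),
                           design = data.frame(
                             instruction = c("accuracy", "speed"),
                             difficulty = c("easy", "easy")))
  av <- condition_averages(ep)
  expect_named(av, c("accuracy.easy.stimulus", "accuracy.easy.response",
                     "speed.easy.stimulus", "speed.easy.response"),
               ignore.order = TRUE)
})

test_that("scale and split fitting recovers generating values from clean signals", {
  p <- quick_params()
  t_er <- unname(p$t_er["accuracy"])
  gen <- function(te) {
    ep <- predict_cpp_traces(p, nondecision_split(te, t_er - te),
                             sim = sim_config(dt = 0.01, n_trials = 600,
                                              seed = 77),
                             design = four_cell_design(600),
                             grid = seq(0, 1.6, 0.01))
    condition_averages(baseline_correct(ep))
  }
  true_te <- 0.21
  observed <- lapply(gen(true_te), function(s) { s$value <- 1.8 * s$value; s })
  fit <- fit_scale_and_split(gen, observed, t_er, n_grid = 8)
  expect_equal(fit$scale, 1.8, tolerance = 0.05)
  expect_equal(fit$split$t_e, true_te, tolerance = 0.03)
  expect_true(fit$converged)
})
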