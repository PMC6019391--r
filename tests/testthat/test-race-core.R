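test_that("a single Euler step adds drift and scaled noise", {
  cond <- condition_params(a = 1, s_z = 0.447, v_correct = 1.28,
                           v_incorrect = 0.098, sigma = 0.499)
  st <- step_accumulators(c(0, 0), cond, dt = 0.01, noise = c(0, 0))
  expect_equal(st, c(0.0128, 0.00098))
  st2 <- step_accumulators(c(0.5, 0.2), cond, dt = 0.01, noise = c(1, -1))
  expect_equal(st2[1], 0.5 + 0.0128 + 0.499 * sqrt(0.01))
  expect_equal(st2[2], 0.2 + 0.00098 - 0.499 * sqrt(0.01))
})

test_that("accumulators are rectified at zero", {
  cond <- condition_params(a = 1, s_z = 0, v_correct = 0.1,
                           v_incorrect = 0.1, sigma = 1)
  st <- step_accumulators(c(0.01, 0.01), cond, dt = 0.01, noise = c(-5, -5))
  expect_identical(unname(st), c(0, 0))
})

test_that("a noiseless ramp crosses the boundary at the deterministic time", {
  p <- ramp_params(v = 2)  # ramp reaches 1 at step 50 (dt 0.01): decision 0.5
  d <- simulate_dataset(p, four_cell_design(20),
                        sim_config(dt = 0.01, n_trials = 20, seed = 4))
  expect_true(all(d$choice == "correct"))
  expect_true(all(abs(d$decision_time - 0.5) < 1e-9))
  expect_true(all(abs(d$rt - 0.8) < 1e-9))  # + t_er = 0.3, s_ter = 0
})

test_that("the faster drift wins every noiseless race", {
  p <- ramp_params(v = 1, vi = 0.9)
  d <- simulate_dataset(p, four_cell_design(10),
                        sim_config(dt = 0.01, n_trials = 10, seed = 1))
  expect_true(all(d$choice == "correct"))
})

test_that("simulation is reproducible given a seed and differs across seeds", {
  p <- quick_params()
  des <- four_cell_design(300)
  d1 <- simulate_dataset(p, des, sim_config(n_trials = 300, seed = 42))
  d2 <- simulate_dataset(p, des, sim_config(n_trials = 300, seed = 42))
  d3 <- simulate_dataset(p, des, sim_config(n_trials = 300, seed = 43))
  expect_identical(d1$rt, d2$rt)
  expect_identical(d1$choice, d2$choice)
  expect_false(identical(d1$rt, d3$rt))
})

test_that("trial indices give independent, order-free substreams", {
  p <- quick_params()
  cond <- cell_params(p, "accuracy", "easy")
  a <- raceSAT:::race_sim_cpp(50, cond$a, cond$s_z, cond$v_correct, cond$v_incorrect,
                    cond$sigma, 0.35, 0.3, 0.01, 500, 9L, 0L)
  b <- raceSAT:::race_sim_cpp(100, cond$a, cond$s_z, cond$v_correct, cond$v_incorrect,
                    cond$sigma, 0.35, 0.3, 0.01, 500, 9L, 0L)
  expect_identical(a$steps, b$steps[1:50])  # prefix stability
  expect_identical(a$ndt, b$ndt[1:50])
})

test_that("non-decision times respect the uniform bounds and compose RT", {
  p <- quick_params()  # t_er 0.35, s_ter 0.3 -> ndt in [0.2, 0.5]
  d <- simulate_dataset(p, four_cell_design(2000),
                        sim_config(n_trials = 2000, seed = 7))
  ndt <- d$rt - d$decision_time
  ndt <- ndt[!is.na(ndt)]
  expect_true(all(ndt >= 0.2 - 1e-12 & ndt <= 0.5 + 1e-12))
  # uniform spread: mean near t_er, both halves populated
  expect_lt(abs(mean(ndt) - 0.35), 0.01)
  expect_gt(min(ndt), 0.19); expect_lt(max(ndt), 0.51)
})

test_that("start points are uniform on [0, S_z)", {
  cond <- condition_params(a = 1, s_z = 0.5, v_correct = 1,
                           v_incorrect = 0.1, sigma = 0.5)
  z <- raceSAT:::race_sim_cpp(5000, cond$a, cond$s_z, cond$v_correct,
                    cond$v_incorrect, cond$sigma, 0.3, 0.1, 0.01, 500, 3L, 0L)
  for (s in list(z$start_correct, z$start_incorrect)) {
    expect_true(all(s >= 0 & s < 0.5))
    expect_lt(abs(mean(s) - 0.25), 0.01)
    expect_lt(abs(var(s) - 0.5^2 / 12), 0.002)
  }
  expect_lt(abs(cor(z$start_correct, z$start_incorrect)), 0.05)
})

test_that("accuracy increases with the correct drift rate", {
  base <- quick_params()
  acc <- vapply(c(0.6, 1.2, 2.4), function(v) {
    p <- race_params(a = 1, s_z = 0.4, v_correct = v, v_incorrect = 0.1,
                     sigma = 0.5, t_er = 0.3, s_ter = 0.2)
    d <- simulate_dataset(p, four_cell_design(5000),
                          sim_config(n_trials = 5000, seed = 11))
    mean(d$choice == "correct")
  }, numeric(1))
  expect_true(all(diff(acc) > 0))
})

test_that("choice probabilities match an independently coded reference simulator", {
  # Expected value frozen from a straight-R vectorized implementation of the
  # same stochastic process (rectified Euler race, uniform start points,
  # 50,000 trials): P(correct) = 0.8398 for the bundled accuracy/hard cell.
  # Tolerance 0.01 is ~4 combined binomial standard errors.
  p <- sat_reference_params("tms")
  des <- data.frame(participant_id = 1, session = 1, instruction = "accuracy",
                    difficulty = "hard", n_trials = 50000)
  d <- simulate_dataset(p, des, sim_config(dt = 0.01, n_trials = 50000,
                                           seed = 777))
  expect_lt(abs(mean(d$choice == "correct") - 0.8398), 0.01)
})

test_that("non-terminating trials are censored as non-responses", {
  p <- race_params(a = 1, s_z = 0, v_correct = 0.01, v_incorrect = 0.01,
                   sigma = 0.05, t_er = 0.3, s_ter = 0)
  d <- simulate_dataset(p, four_cell_design(200),
                        sim_config(n_trials = 200, max_time = 0.5, seed = 2))
  expect_gt(sum(d$choice == "none"), 0)
  expect_true(all(is.na(d$rt[d$choice == "none"])))
  expect_true(all(!is.na(d$rt[d$choice != "none"])))
})

test_that("behavior is invariant to a common scaling of evidence parameters", {
  p <- quick_params()
  c_fac <- 2.37
  sc <- p
  for (col in c("a", "s_z", "v_correct", "v_incorrect", "sigma"))
    sc$cells[[col]] <- p$cells[[col]] * c_fac
  des <- four_cell_design(1000)
  sim <- sim_config(n_trials = 1000, seed = 123)
  d1 <- simulate_dataset(p, des, sim)
  d2 <- simulate_dataset(sc, des, sim)
  expect_identical(d1$choice, d2$choice)
  expect_identical(d1$rt, d2$rt)
})
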