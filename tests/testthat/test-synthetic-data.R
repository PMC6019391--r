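small_design <- function() study_design(n_participants = 3, n_trials_cell = 40)

test_that("generated behavior covers the design and is reproducible", {
  p <- quick_params()
  beh1 <- generate_behavior(p, small_design(), sim_config(dt = 0.005, seed = 21))
  beh2 <- generate_behavior(p, small_design(), sim_config(dt = 0.005, seed = 21))
  expect_identical(beh1$rt, beh2$rt)
  expect_equal(nrow(beh1), 3 * 4 * 40)
  expect_equal(sort(unique(beh1$participant_id)), 1:3)
  tab <- table(beh1$instruction, beh1$difficulty)
  expect_true(all(tab == 3 * 40))
  resp <- beh1$choice != "none"
  expect_equal(beh1$rt[resp], beh1$decision_time[resp] +
                 (beh1$rt - beh1$decision_time)[resp])
  blocks <- attr(beh1, "blocks")
  expect_equal(nrow(blocks), 12)
  expect_equal(sum(blocks$n), nrow(beh1))
})

test_that("participant non-decision means are jittered within the declared band", {
  p <- quick_params()  # t_er = 0.35
  des <- study_design(n_participants = 6, n_trials_cell = 10, t_er_jitter = 0.05)
  beh <- generate_behavior(p, des, sim_config(dt = 0.005, seed = 2))
  blocks <- attr(beh, "blocks")
  expect_true(all(blocks$t_er >= 0.35 * 0.95 - 1e-12 &
                    blocks$t_er <= 0.35 * 1.05 + 1e-12))
  # all cells of one participant share that participant's value
  per <- tapply(blocks$t_er, blocks$participant_id,
                function(v) diff(range(v)))
  expect_true(all(per < 1e-12))
})

test_that("pulse schedules respect the per-instruction windows and cancellation", {
  p <- quick_params()
  beh <- generate_behavior(p, small_design(), sim_config(dt = 0.005, seed = 5))
  sch <- generate_tms_schedule(beh, small_design(), seed = 6)
  for (ins in c("accuracy", "speed")) {
    w <- small_design()$stim_windows[[ins]]
    lat <- sch$tms_latency[sch$instruction == ins]
    expect_true(all(lat >= w[1] & lat <= w[2]))
  }
  resp <- !is.na(sch$rt)
  expect_identical(sch$delivered[resp], sch$rt[resp] >= sch$tms_latency[resp])
  expect_true(all(sch$delivered[!resp]))
})

test_that("a noiseless read-out reproduces the latent accumulator states", {
  p <- quick_params()
  beh <- generate_behavior(p, small_design(), sim_config(dt = 0.005, seed = 31))
  sch <- generate_tms_schedule(beh, small_design(), seed = 32)
  rec <- generate_mep_records(sch, readout_model(mep_baseline = 0, mep_gain = 1,
                                                 mep_noise_sd = 0), seed = 33)
  # two rows per delivered responded trial
  keep <- sch$delivered & sch$choice %in% c("correct", "incorrect")
  expect_equal(nrow(rec), 2 * sum(keep))
  expect_setequal(unique(rec$muscle_role), c("responding", "nonresponding"))
  # pulses before the earliest possible accumulation onset read exactly zero
  ndt_min <- min(attr(beh, "blocks")$t_er) - p$s_ter / 2
  early <- rec$tms_latency < ndt_min - 1e-9
  expect_gt(sum(early), 0)
  expect_true(all(rec$amplitude[early] == 0))
  # late pulses on responding muscles read out sizeable accumulation
  resp_rows <- rec$muscle_role == "responding" & rec$tms_latency > 0.8
  expect_gt(mean(rec$amplitude[resp_rows]), 0.3)
})

test_that("difference records from the generator pair every delivered trial", {
  p <- quick_params()
  beh <- generate_behavior(p, small_design(), sim_config(dt = 0.005, seed = 41))
  sch <- generate_tms_schedule(beh, small_design(), seed = 42)
  rec <- generate_mep_records(sch, readout_model(), seed = 43)
  z <- zscore_amplitudes(rec, by = "muscle_role")
  d <- difference_records(z)
  expect_equal(nrow(d), nrow(rec) / 2)
  expect_true(all(c("instruction", "difficulty", "rt") %in% names(d)))
})

test_that("synthetic epochs replay behavioral trials and carry AR(1) noise", {
  p <- quick_params()
  beh <- generate_behavior(p, small_design(), sim_config(dt = 0.005, seed = 51))
  sp <- nondecision_split(0.35 - 0.08, 0.08)
  ro <- readout_model(cpp_noise_sd = 0.2, cpp_ar = 0.8)
  ep <- generate_cpp_epochs(beh, sp, ro, grid = seq(0, 2, 0.005), seed = 52)
  resp <- !is.na(beh$rt)
  expect_equal(ep$trials$rt[resp], beh$rt[resp], tolerance = 1e-9)
  # samples after the response are masked
  i <- which(resp)[1]
  rt_i <- ep$trials$rt[i]
  expect_true(all(is.na(ep$amplitude[i, ep$times > rt_i + 0.006])))
  # pre-onset samples contain only noise: check scale and autocorrelation
  onset_min <- (0.35 * 0.95 - 0.35 / 2) - sp$t_r  # conservative bound
  pre <- ep$amplitude[, ep$times < 0.05, drop = FALSE]
  pre <- pre[!is.na(pre[, 1]), ]
  expect_equal(sd(as.vector(pre)), 0.2, tolerance = 0.02)
  r1 <- cor(as.vector(pre[, -1]), as.vector(pre[, -ncol(pre)]))
  expect_equal(r1, 0.8, tolerance = 0.03)
})

test_that("epoch generation is deterministic and respects the noiseless limit", {
  p <- quick_params()
  des <- study_design(n_participants = 2, n_trials_cell = 15)
  beh <- generate_behavior(p, des, sim_config(dt = 0.005, seed = 61))
  sp <- nondecision_split(0.3, 0.05)
  ro0 <- readout_model(cpp_gain = 2, cpp_noise_sd = 0)
  e1 <- generate_cpp_epochs(beh, sp, ro0, seed = 62)
  e2 <- generate_cpp_epochs(beh, sp, ro0, seed = 99)  # noise seed irrelevant at sd 0
  expect_equal(e1$amplitude, e2$amplitude)
  # noiseless amplitudes are non-negative multiples of summed accumulators
  expect_true(all(e1$amplitude >= -1e-12, na.rm = TRUE))
})
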