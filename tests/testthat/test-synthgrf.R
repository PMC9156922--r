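# The trial generator's ground truth must obey the running-speed identity
# and the impulse-balance peak by construction; the emitted signal must
# integrate to the same stance average.

test_that("symmetric config has zero true symmetry indices", {
  sim <- clean_sim()
  expect_equal(unname(sim$truth$si), c(0, 0, 0))
})

test_that("impulse balance sets the half-sine peak analytically", {
  # t_c = 0.2 s, t_a = 0.12 s: F_avg = 0.32/0.2 = 1.6 BW, and the half-sine
  # mean (2/pi) F_peak must equal 1.6 m g
  m <- 70; g <- 9.81
  sim <- clean_sim(body_mass = m)
  expect_equal(sim$truth$steps$F_avg, rep(1.6, 16))
  expect_equal(sim$truth$steps$f_peak, rep((pi / 2) * 1.6 * m * g, 16))
  # numerical integration of the generated samples over a true stance window
  st <- sim$truth$steps[1, ]
  idx <- which((seq_along(sim$grf$force) - 1) / 1000 >= st$touchdown_t &
               (seq_along(sim$grf$force) - 1) / 1000 < st$takeoff_t)
  f_avg_num <- mean(sim$grf$force[idx]) / (m * g)
  expect_lt(abs(f_avg_num - (st$t_c + st$t_a) / st$t_c) / 1.6, 1e-3)
})

test_that("truth satisfies v = L_c * F_avg * f_step to 1e-9", {
  for (v in c(3, 5, 7)) {
    sim <- clean_sim(belt_speed = v, t_c = 0.25 - 0.02 * v, t_a = 0.1 + 0.005 * v)
    st <- sim$truth$steps
    expect_lt(max(abs(v - st$L_c * st$F_avg * st$f_step)), 1e-9)
  }
  # worked case: v = 3, t_c = 0.2, t_a = 0.12
  sim <- clean_sim()
  expect_equal(sim$truth$steps$L_c[1], 0.6)
  expect_equal(sim$truth$steps$f_step[1], 3.125)
  expect_equal(0.6 * 1.6 * 3.125, 3)
})

test_that("between-leg offsets give the closed-form symmetry indices", {
  # +/-10% multiplicative t_c offset: UL = 1.1x, AL = 0.9x
  sim <- simulate_trial(sim_trial_config(3, 70, asymmetry = list(t_c = 0.1)))
  tcu <- 0.2 * 1.1; tca <- 0.2 * 0.9
  expect_equal(unname(sim$truth$si["L_c"]), 20)   # 0.2x / (0.5 * 2x) * 100
  expect_equal(unname(sim$truth$si["f_step"]),
               symmetry_index(1 / (tcu + 0.12), 1 / (tca + 0.12)))
  expect_equal(unname(sim$truth$si["F_avg"]),
               symmetry_index((tcu + 0.12) / tcu, (tca + 0.12) / tca))
  # peak offset moves only F_avg
  sim2 <- simulate_trial(sim_trial_config(3, 70, asymmetry = list(peak = 0.1)))
  expect_equal(unname(sim2$truth$si), c(0, 20, 0))
})

test_that("identical seeds give identical output, different seeds differ", {
  cfg <- sim_trial_config(3, 70, noise_sd = 5, seed = 42)
  expect_identical(simulate_trial(cfg), simulate_trial(cfg))
  cfg2 <- sim_trial_config(3, 70, noise_sd = 5, seed = 43)
  expect_false(identical(simulate_trial(cfg)$grf$force,
                         simulate_trial(cfg2)$grf$force))
})

test_that("unusable configurations are rejected", {
  expect_error(sim_trial_config(3, 70, saturation_level = 500),
               "below body weight")
  cfg <- sim_trial_config(3, 70, t_c = 0.003)
  expect_error(simulate_trial(cfg), "4 force samples")
  expect_error(sim_trial_config(3, 70, asymmetry = list(bogus = 1)), "bogus")
})

test_that("study design emulation reproduces the analysed-trial accounting", {
  d <- rsp_study_design()
  expect_equal(sum(!d$saturated), 704)
  expect_equal(sum(d$saturated), 4)
  expect_equal(sort(unique(d$subject)), sprintf("S%02d", 1:10))
  # individual height deviations pass through as signed non-integer cm
  expect_true(all(c(-1.8, -1.3, -1, 0.8, 1) %in% d$height_offset_cm))
  # recommended-height cells contain all 10 subjects for all 9 configs
  rec <- d[d$height_offset_cm == 0, ]
  expect_equal(nrow(unique(rec[, c("subject", "rsp_model", "stiffness_cat")])),
               90)
})

test_that("trial-table simulation is the stated linear predictor", {
  des <- balanced_design(2)
  # all coefficients zero except intercept, no noise
  tab <- simulate_trial_table(lmm_sim_config(c(intercept = 1.23), design = des))
  expect_equal(tab$response, rep(1.23, nrow(des)))
  # speed slope 0.066: response difference between 7 and 3 m/s rows = 0.264
  tab2 <- simulate_trial_table(lmm_sim_config(
    c(intercept = 0.5, `speed [m s^-1]` = 0.066), design = des))
  base <- tab2[tab2$rsp_model == "Catapult" & tab2$stiffness_cat == "-1" &
               tab2$height_offset_cm == 0 & tab2$subject == "S01", ]
  expect_equal(base$response[base$speed == 7] - base$response[base$speed == 3],
               0.264)
  # unknown term rejected by name
  expect_error(lmm_sim_config(c(`speed slope` = 1)), "speed slope")
  # deterministic under seed
  cfg <- lmm_sim_config(lc_truth(), subject_sd = 0.02, residual_sd = 0.02,
                        seed = 7)
  expect_identical(simulate_trial_table(cfg), simulate_trial_table(cfg))
})
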