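# Signal conditioning: zero-phase filtering, drift correction, stance
# detection against the analytic half-sine oracle, and leg labelling.

test_that("zero-phase Butterworth has unit DC gain and the expected roll-off", {
  fs <- 1000
  expect_equal(lowpass(rep(700, 2000), 30, fs), rep(700, 2000))
  tt <- (0:3999) / fs
  mid <- 1000:3000
  # 5 Hz passband tone: < 1% attenuation, zero phase lag at the peak
  x5 <- sin(2 * pi * 5 * tt)
  y5 <- lowpass(x5, 30, fs)
  expect_lt(abs(max(y5[mid]) - max(x5[mid])), 0.01)
  # zero phase: the peak at t = 2.05 s (analytic crest) stays put
  crest <- 1950:2150
  expect_lt(abs(which.max(y5[crest]) - which.max(x5[crest])), 2)
  # 100 Hz stopband tone: two passes of |H|^2 = 1/(1+(100/30)^8) => > 99%
  y100 <- lowpass(sin(2 * pi * 100 * tt), 30, fs)
  expect_lt(max(abs(y100[mid])), 0.01)
  expect_error(lowpass(x5, 500, fs), "Nyquist")
})

test_that("drift correction restores the aerial baseline", {
  sim <- clean_sim()
  f <- sim$grf$force
  # true zero baseline: output ~ input
  expect_lt(max(abs(correct_drift(f, sample_rate = 1000) - f)), 0.5)
  # 0 -> 10 N linear ramp: corrected aerial medians back to +/- 0.5 N and
  # stance averages within 0.5% of the undrifted reference
  drifted <- f + seq(0, 10, length.out = length(f))
  corr <- correct_drift(drifted, sample_rate = 1000)
  aer <- corr[f < 20]
  expect_lt(abs(median(aer)), 0.5)
  st <- sim$truth$steps[3, ]
  idx <- which((seq_along(f) - 1) / 1000 >= st$touchdown_t &
               (seq_along(f) - 1) / 1000 < st$takeoff_t)
  expect_lt(abs(mean(corr[idx]) - mean(f[idx])) / mean(f[idx]), 0.005)
  # constant signal: no aerial phase at all
  expect_error(correct_drift(rep(500, 3000), sample_rate = 1000),
               "no aerial baseline")
})

test_that("stance edges match the analytic threshold-crossing solve", {
  # F(t) = 1500 sin(pi t / 0.2) crosses 20 N at t1 = (0.2/pi) asin(20/1500)
  x <- half_sine_signal(f_peak = 1500, t_c = 0.2)
  ev <- detect_stance(x, sample_rate = 1000)
  expect_equal(nrow(ev), 1)
  t_c_analytic <- 0.2 - 2 * (0.2 / pi) * asin(20 / 1500)
  expect_lte(abs(ev$t_c - t_c_analytic), 2 / 1000)  # +/- 1 sample per edge
})

test_that("detection handles empty, sub-threshold and interrupted signals", {
  expect_equal(nrow(detect_stance(numeric(0), sample_rate = 1000)), 0)
  expect_equal(nrow(detect_stance(rep(0, 5000), sample_rate = 1000)), 0)
  expect_equal(nrow(detect_stance(rep(5, 5000), sample_rate = 1000)), 0)
  # 5 ms mid-stance dropout is debounced into one event
  x <- half_sine_signal()
  x[995:999] <- 0
  ev <- detect_stance(x, sample_rate = 1000, min_aerial = 0.02)
  expect_equal(nrow(ev), 1)
  # a too-short burst is discarded
  x2 <- numeric(3000); x2[1500:1520] <- 100
  expect_equal(nrow(detect_stance(x2, sample_rate = 1000)), 0)
  # stances touching a signal edge are incomplete and dropped
  x3 <- c(rep(100, 200), numeric(2000), rep(100, 200))
  expect_equal(nrow(detect_stance(x3, sample_rate = 1000)), 0)
})

test_that("events partition time: ordered, non-overlapping", {
  sim <- clean_sim(belt_speed = 7, t_c = 0.11, t_a = 0.14,
                   noise_sd = 4, seed = 9)
  pr <- process_quiet(sim$grf, sim$markers)
  ev <- pr$events
  expect_true(all(ev$takeoff > ev$touchdown))
  expect_true(all(diff(ev$touchdown) > 0))
  expect_true(all(ev$touchdown[-1] >= ev$takeoff[-nrow(ev)]))
})

test_that("round trip: detected timings match simulation truth within 2 samples per edge", {
  for (v in c(3, 7)) {
    sim <- clean_sim(belt_speed = v, t_c = if (v == 3) 0.2 else 0.11,
                     t_a = if (v == 3) 0.12 else 0.14)
    pr <- process_quiet(sim$grf, sim$markers)
    true_td <- round(sim$truth$steps$touchdown_t * 1000) + 1
    true_to <- round(sim$truth$steps$takeoff_t * 1000) + 1
    expect_lte(max(abs(pr$events$touchdown - true_td)), 2)
    expect_lte(max(abs(pr$events$takeoff - true_to)), 2)
    expect_lte(max(abs(pr$events$t_c - sim$truth$steps$t_c)), 4 / 1000)
    ta_err <- abs(pr$events$t_a - sim$truth$steps$t_a)
    expect_lte(max(ta_err, na.rm = TRUE), 4 / 1000)
  }
})

test_that("detection is invariant to drift that correct_drift removes", {
  sim <- clean_sim()
  f <- sim$grf$force
  ref <- detect_stance(correct_drift(f, sample_rate = 1000), sample_rate = 1000)
  drifted <- correct_drift(f + seq(0, 10, length.out = length(f)),
                           sample_rate = 1000)
  ev <- detect_stance(drifted, sample_rate = 1000)
  expect_equal(nrow(ev), nrow(ref))
  expect_lte(max(abs(ev$touchdown - ref$touchdown)), 1)
  expect_lte(max(abs(ev$takeoff - ref$takeoff)), 1)
})

test_that("filtering then detecting a time-reversed signal reverses the events", {
  sim <- clean_sim(t_c = 0.18, t_a = 0.13)
  y <- lowpass(sim$grf$force, 30, 1000)
  n <- length(y)
  ev <- detect_stance(y, sample_rate = 1000)
  rv <- detect_stance(rev(y), sample_rate = 1000)
  expect_equal(nrow(rv), nrow(ev))
  # half-open [touchdown, takeoff) maps to [n + 2 - takeoff, n + 2 - touchdown)
  expect_equal(rv$touchdown, rev(n + 2L - ev$takeoff))
  expect_equal(rv$takeoff, rev(n + 2L - ev$touchdown))
})

test_that("legs are labelled from the marker heights and alternation is guarded", {
  sim <- clean_sim(first_leg = "affected")
  pr <- process_quiet(sim$grf, sim$markers)
  expect_equal(pr$events$leg,
               rep(c("affected", "unaffected"), length.out = nrow(pr$events)))
  # no markers at all: strict alternation from the fallback seed label
  ev <- detect_stance(correct_drift(sim$grf), sample_rate = 1000)
  ev2 <- assign_legs(ev, markers = NULL)
  expect_equal(ev2$leg, rep(c("affected", "unaffected"), length.out = nrow(ev2)))
  # markers that resolve two consecutive stances to the same leg
  ev3 <- ev[1:2, ]
  low <- marker_trial(affected = rep(0.05, 1500), unaffected = rep(0.15, 1500),
                      sample_rate = 200)
  expect_warning(ev3 <- assign_legs(ev3, low, force_rate = 1000),
                 "alternation")
  expect_equal(ev3$leg, c("affected", "unknown"))
})

test_that("saturated trials are flagged and excluded from aggregation", {
  cfg <- sim_trial_config(3, 70, saturation_level = 1200)
  sim <- simulate_trial(cfg)   # impulse-balance peak ~1725 N: clipped
  expect_true(is_saturated(sim$grf))
  pr <- process_quiet(sim$grf, sim$markers)
  expect_true(pr$qc$saturated)
  # an unclipped trial is not flagged
  expect_false(is_saturated(clean_sim()$grf, level = 5000))
})
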