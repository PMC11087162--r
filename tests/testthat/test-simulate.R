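test_that("noiseless motion has exact amplitude and peak spacing", {
  cfg <- quiet_config(amplitude = 10, period = 3, n_cycles = 4)
  t <- gatelat:::session_time_axis(cfg)
  x <- simulate_motion(cfg)
  expect_equal(max(x) - min(x), 10.0, tolerance = 1e-12)
  # peaks at integer multiples of the period
  pk <- t[x == max(x)]
  expect_true(all(abs(pk - round(pk / 3) * 3) < 1e-9))
  # half-period padding keeps first/last peaks interior
  expect_lt(t[1], 0)
  expect_gt(t[length(t)], 4 * 3)
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- noisy_config(seed = 42, n_cycles = 3)
  s1 <- simulate_session(cfg)
  s2 <- simulate_session(cfg)
  expect_identical(s1$recording, s2$recording)
  expect_identical(s1$truth, s2$truth)
  expect_identical(simulate_motion(cfg), simulate_motion(cfg))
  s3 <- simulate_session(noisy_config(seed = 43, n_cycles = 3))
  expect_false(identical(s1$recording$motion, s3$recording$motion))
})

test_that("fraction of samples above the 90% threshold matches acos(0.8)/pi", {
  cfg <- quiet_config(amplitude = 15, period = 3, n_cycles = 6)
  x <- simulate_motion(cfg)
  frac <- mean(x >= min(x) + 0.9 * (max(x) - min(x)))
  # interior portion of the trace holds full cycles plus two half-caps that
  # together make one more peak: (n_cycles + 1) caps over (n_cycles + 1)
  # periods of record
  expect_equal(frac, acos(0.8) / pi, tolerance = 1e-3)
})

test_that("ground truth has one row per cycle and the exact gate identity", {
  cfg <- noisy_config(amplitude = 15, period = 3, n_cycles = 30, seed = 7)
  ses <- simulate_session(cfg)
  tr <- ses$truth
  expect_identical(nrow(tr), 30L)
  expect_equal(tr$true_gate_open_time, tr$true_peak_time + 0.40 * 3)
  expect_equal(tr$true_gate_close_time, tr$true_peak_time + 0.60 * 3)
})

test_that("injected component latencies add exactly to the true totals", {
  ses <- simulate_session(noisy_config(n_cycles = 20, seed = 11))
  tr <- ses$truth
  expect_equal((tr$true_beam_on - tr$true_gate_open_time) * 1000,
               tr$injected_rpm_on + tr$injected_cyc_on, tolerance = 1e-9)
  expect_equal((tr$true_beam_off - tr$true_gate_close_time) * 1000,
               tr$injected_rpm_off + tr$injected_cyc_off, tolerance = 1e-9)
})

test_that("zero-latency noiseless session puts the trigger edge at gate open", {
  cfg <- quiet_config(rpm_on = 0, rpm_off = 0, cyc_on = 0, cyc_off = 0,
                      n_cycles = 3)
  ses <- simulate_session(cfg)
  rec <- ses$recording
  dt <- 1 / cfg$sampling_rate
  for (i in seq_len(nrow(ses$truth))) {
    t_open <- ses$truth$true_gate_open_time[i]
    # first sample where the trigger leaves 0 V
    j <- which(rec$time > t_open - 0.05 & rec$trigger > 0)[1]
    expect_lte(abs(rec$time[j] - t_open), dt + 1e-12)
  }
})

test_that("constant injected means reproduce the published total by construction", {
  cfg <- quiet_config(rpm_on = 104.20, cyc_on = 108.29, n_cycles = 4)
  tr <- simulate_session(cfg)$truth
  expect_equal((tr$true_beam_on - tr$true_gate_open_time) * 1000,
               rep(212.49, 4), tolerance = 1e-9)
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(scenario_config(amplitude = -5, period = 3),
               "amplitude", class = "gatelat_config_error")
  expect_error(scenario_config(amplitude = 10, period = 0),
               "period", class = "gatelat_config_error")
  expect_error(scenario_config(amplitude = 10, period = 3,
                               sampling_rate = 100),
               "sampling_rate", class = "gatelat_config_error")
  expect_error(scenario_config(amplitude = 10, period = 3,
                               gate_open_phase = 0.7,
                               gate_close_phase = 0.6),
               "gate_open_phase", class = "gatelat_config_error")
  expect_error(scenario_config(amplitude = 10, period = 3,
                               rpm_on_latency_mean = -1),
               "rpm_on_latency_mean", class = "gatelat_config_error")
})

test_that("a gating window narrower than the transition ramps is rejected", {
  cfg <- quiet_config(amplitude = 10, period = 3)
  cfg$gate_open_phase <- 0.5
  cfg$gate_close_phase <- 0.5001  # 0.3 ms window < two ramps + 2 samples
  expect_error(simulate_session(cfg), class = "gatelat_infeasible_scenario_error")
})
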