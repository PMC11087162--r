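matched_row <- function(gate_open, gate_close, trig_on, trig_off,
                        beam_on, beam_off) {
  data.frame(cycle = 1L, peak_time = gate_open - 1.2, cycle_period = 3,
             gate_open_time = gate_open, gate_close_time = gate_close,
             plausible = TRUE, trigger_on = trig_on,
             trigger_off = trig_off, beam_on = beam_on,
             beam_off = beam_off,
             complete = !anyNA(c(trig_on, trig_off, beam_on, beam_off)))
}

test_that("latency arithmetic reproduces the worked three-timestamp example", {
  m <- matched_row(1.2000, 1.8000, 1.3042, 1.9136, 1.4126, 1.9148)
  lat <- compute_latencies(m)
  expect_equal(lat$tau_rpm_on, 104.2, tolerance = 1e-9)
  expect_equal(lat$tau_cyc_on, 108.4, tolerance = 1e-9)
  expect_equal(lat$tau_total_on, 212.6, tolerance = 1e-9)
  expect_equal(lat$tau_rpm_off, 113.6, tolerance = 1e-9)
  expect_equal(lat$tau_cyc_off, 1.2, tolerance = 1e-9)
  expect_equal(lat$tau_total_off, 114.8, tolerance = 1e-9)
})

test_that("coincident trigger and gate times give zero gating latency", {
  m <- matched_row(1.2, 1.8, 1.2, 1.8, 1.31, 1.801)
  lat <- compute_latencies(m)
  expect_identical(lat$tau_rpm_on, 0)
  expect_identical(lat$tau_rpm_off, 0)
})

test_that("totals are the bit-exact sum of their components", {
  ses <- simulate_session(noisy_config(n_cycles = 15, seed = 4))
  lat <- recover_from_session(ses$recording)$latencies
  expect_identical(lat$tau_total_on, lat$tau_rpm_on + lat$tau_cyc_on)
  expect_identical(lat$tau_total_off, lat$tau_rpm_off + lat$tau_cyc_off)
})

test_that("negative gating latency is reported, not clamped, with a warning", {
  m <- matched_row(1.2, 1.8, 1.15, 1.9, 1.26, 1.901)
  expect_warning(lat <- compute_latencies(m),
                 class = "gatelat_negative_latency_warning")
  expect_equal(lat$tau_rpm_on, -50, tolerance = 1e-9)
})

test_that("noiseless zero-latency session recovers all-zero latencies", {
  cfg <- quiet_config(rpm_on = 0, rpm_off = 0, cyc_on = 0, cyc_off = 0,
                      n_cycles = 4)
  ses <- simulate_session(cfg)
  lat <- suppressWarnings(recover_from_session(ses$recording)$latencies)
  for (col in c("tau_rpm_on", "tau_rpm_off", "tau_cyc_on", "tau_cyc_off"))
    expect_lt(max(abs(lat[[col]])), 0.2)
})

test_that("noiseless constant injections are recovered within 0.5 ms", {
  cfg <- quiet_config(rpm_on = 104, rpm_off = 113, cyc_on = 108,
                      cyc_off = 1.2, n_cycles = 5)
  ses <- simulate_session(cfg)
  lat <- recover_from_session(ses$recording)$latencies
  expect_lt(abs(mean(lat$tau_rpm_on) - 104), 0.5)
  expect_lt(abs(mean(lat$tau_rpm_off) - 113), 0.5)
  expect_lt(abs(mean(lat$tau_cyc_on) - 108), 0.5)
  expect_lt(abs(mean(lat$tau_cyc_off) - 1.2), 0.5)
})

test_that("default-noise session recovers injected means within 3 ms", {
  cfg <- noisy_config(n_cycles = 30, seed = 8)
  ses <- simulate_session(cfg)
  lat <- recover_from_session(ses$recording)$latencies
  tr <- ses$truth
  expect_lt(abs(mean(lat$tau_rpm_on) - mean(tr$injected_rpm_on)), 3)
  expect_lt(abs(mean(lat$tau_rpm_off) - mean(tr$injected_rpm_off)), 3)
  expect_lt(abs(mean(lat$tau_cyc_on) - mean(tr$injected_cyc_on)), 3)
  expect_lt(abs(mean(lat$tau_cyc_off) - mean(tr$injected_cyc_off)), 3)
})

test_that("latencies are invariant to a constant time-axis shift", {
  ses <- simulate_session(quiet_config(n_cycles = 4))
  rec <- ses$recording
  base <- recover_from_session(rec)$latencies
  rec$time <- rec$time + 1234.5
  shifted <- recover_from_session(rec)$latencies
  for (col in c("tau_rpm_on", "tau_rpm_off", "tau_cyc_on", "tau_cyc_off"))
    expect_equal(shifted[[col]], base[[col]], tolerance = 1e-6)
})

test_that("pipeline errors carry the failing stage name", {
  rec <- gatelat:::new_recording(time = (0:9999) / 1e4,
                                 motion = rep(1, 10000),
                                 trigger = rep(0, 10000),
                                 beam = rep(0, 10000),
                                 sampling_rate = 1e4)
  err <- tryCatch(recover_from_session(rec), error = identity)
  expect_s3_class(err, "gatelat_pipeline_error")
  expect_match(conditionMessage(err), "\\[phases\\]")
})
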