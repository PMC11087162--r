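make_step <- function(fs = 10000, t_on = 2.0, t_off = 2.6, level = 12,
                      rise = 0, dur = 4) {
  t <- (0:(dur * fs)) / fs
  x <- gatelat:::square_channel(t, t_on, t_off, level, rise)
  list(t = t, x = x)
}

test_that("an ideal step is timestamped within one sample", {
  s <- make_step(rise = 0)
  ev <- detect_edges(s$x, s$t)
  expect_identical(ev$direction, c("rising", "falling"))
  expect_lte(abs(ev$timestamp[1] - 2.0), 1e-4)
  expect_lte(abs(ev$timestamp[2] - 2.6), 1e-4)
})

test_that("a linear ramp is timestamped at its interpolated 20%/80% crossings", {
  # 0 -> 12 V over 1 ms starting at t = 2.000 s: 20% crossing at 2.0002
  s <- make_step(rise = 1e-3)
  ev <- detect_edges(s$x, s$t)
  expect_equal(ev$timestamp[1], 2.0002, tolerance = 1e-7)
  # falling edge: 80% crossing on the descent starting 2.6, also +0.2 ms
  expect_equal(ev$timestamp[2], 2.6002, tolerance = 1e-7)
  expect_equal(ev$threshold_level, c(0.2 * 12, 0.8 * 12), tolerance = 0.01)
})

test_that("single-sample glitches are debounced away", {
  s <- make_step()
  x <- s$x
  x[5000] <- 12           # lone spike amid the LOW baseline
  ev <- detect_edges(x, s$t, percentile_range = FALSE)
  expect_identical(nrow(ev), 2L)
  expect_gt(min(diff(ev$timestamp)), 5e-3)
})

test_that("degenerate channels raise classed errors", {
  t <- (0:1000) / 1e4
  expect_error(detect_edges(rep(0, 1001), t),
               class = "gatelat_no_edges_error")
  set.seed(1)
  noisy_flat <- rnorm(5001, sd = 0.5)
  expect_error(detect_edges(noisy_flat, (0:5000) / 1e4),
               class = "gatelat_low_snr_error")
})

test_that("edge directions alternate and timestamps scale-invariantly", {
  ses <- simulate_session(noisy_config(n_cycles = 6, seed = 21))
  rec <- ses$recording
  ev <- detect_edges(rec$trigger, rec$time)
  expect_true(all(ev$direction[-1] != ev$direction[-nrow(ev)]))
  expect_true(all(diff(ev$timestamp) > 5e-3))
  ev_scaled <- detect_edges(rec$trigger * 4.2, rec$time)
  expect_equal(ev_scaled$timestamp, ev$timestamp, tolerance = 1e-9)
})

test_that("detected transitions match simulator ground truth", {
  cfg <- noisy_config(n_cycles = 8, seed = 13)
  ses <- simulate_session(cfg)
  rec <- ses$recording
  tol <- max(1 / cfg$sampling_rate, cfg$trigger_rise_time / 1000)
  ev <- detect_edges(rec$trigger, rec$time)
  rises <- ev$timestamp[ev$direction == "rising"]
  falls <- ev$timestamp[ev$direction == "falling"]
  expect_length(rises, 8)
  expect_lt(max(abs(rises - ses$truth$true_trigger_on)), tol + 1e-9)
  expect_lt(max(abs(falls - ses$truth$true_trigger_off)), tol + 1e-9)
  bv <- detect_edges(rec$beam, rec$time)
  expect_lt(max(abs(bv$timestamp[bv$direction == "rising"] -
                    ses$truth$true_beam_on)), tol + 1e-9)
})

test_that("event pairing flags cycles whose beam never fires", {
  cfg <- quiet_config(n_cycles = 5)
  ses <- simulate_session(cfg)
  rec <- ses$recording
  cycles <- locate_cycles(preprocess_motion(rec))
  trig <- detect_edges(rec$trigger, rec$time)
  beam <- detect_edges(rec$beam, rec$time)
  matched <- pair_gate_events(cycles, trig, beam)
  expect_true(all(matched$complete))
  expect_identical(nrow(matched), 5L)

  # remove the third beam pulse: that cycle is incomplete, others untouched
  beam2 <- beam[-(5:6), ]
  matched2 <- pair_gate_events(cycles, trig, beam2)
  expect_identical(sum(matched2$complete), 4L)
  expect_false(matched2$complete[3])
})

test_that("a trigger edge exactly on the search-window boundary is included", {
  cycles <- data.frame(cycle = 1L, peak_time = 0, cycle_period = 3,
                       gate_open_time = 1.2, gate_close_time = 1.8,
                       plausible = TRUE)
  # window is [1.2 - 0.75, 1.2 + 1.5]; place the rising edge at the lower bound
  trig <- data.frame(direction = c("rising", "falling"),
                     timestamp = c(0.45, 1.9), threshold_level = 2.4)
  beam <- data.frame(direction = c("rising", "falling"),
                     timestamp = c(0.56, 1.91), threshold_level = 0.02)
  m <- pair_gate_events(cycles, trig, beam)
  expect_true(m$complete)
  expect_equal(m$trigger_on, 0.45)
})
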