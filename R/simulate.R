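#' Define a synthetic motion/gating scenario
#'
#' Builds a validated configuration for the three-channel session simulator.
#' The simulated platform reproduces the geometry of a gating latency QA
#' measurement: a stage performs vertical sinusoidal motion, an optical
#' gating system emits a two-state 0 V / 12 V beam-permission trigger once
#' the surrogate enters a phase-defined gating window, and a beam detector
#' sees an approximately 100 mV step while the beam is actually on.
#'
#' Latencies are injected per cycle: the trigger transition lags the true
#' gate boundary by a draw from a zero-truncated normal distribution
#' (the gating-system latency), and the beam transition lags the trigger by
#' a second independent draw (the treatment-system latency).
#'
#' @param amplitude Peak-to-peak motion amplitude in mm.
#' @param period Motion period in seconds.
#' @param n_cycles Number of full motion cycles to simulate.
#' @param sampling_rate Sampling rate in Hz (all channels share it).
#' @param gate_open_phase,gate_close_phase Gating window as fractions of the
#'   cycle elapsed since the preceding motion peak (peak = phase 0).
#' @param rpm_on_latency_mean,rpm_on_latency_sd Gating-system beam-ON latency
#'   distribution, ms.
#' @param rpm_off_latency_mean,rpm_off_latency_sd Gating-system beam-OFF
#'   latency distribution, ms.
#' @param cyc_on_latency_mean,cyc_on_latency_sd Treatment-system (cyclotron)
#'   beam-ON latency distribution, ms.
#' @param cyc_off_latency_mean,cyc_off_latency_sd Treatment-system beam-OFF
#'   latency distribution, ms.
#' @param trigger_high_level Trigger HIGH voltage, V.
#' @param trigger_rise_time Linear ramp duration of trigger transitions, ms.
#' @param beam_step_level Beam-detector step while beam is on, V.
#' @param beam_rise_time Linear ramp duration of beam transitions, ms.
#' @param noise_motion_sd Gaussian noise on the motion channel, mm.
#' @param powerline_freq Mains interference frequency, Hz.
#' @param powerline_amplitude Mains interference amplitude on the motion
#'   channel, mm.
#' @param spike_rate Rate of single-sample outlier artifacts on the motion
#'   channel, events per second (amplitude 5 x `noise_motion_sd`).
#' @param noise_trigger_sd,noise_beam_sd Gaussian channel noise, V.
#' @param seed Integer seed; identical config + seed gives a bit-identical
#'   session. `NULL` leaves the RNG state alone.
#' @return An object of class `scenario_config` (a validated list).
#' @seealso [simulate_session()], [simulate_motion()]
#' @export
#' @examples
#' cfg <- scenario_config(amplitude = 15, period = 3, n_cycles = 5, seed = 1)
#' ses <- simulate_session(cfg)
#' ses$truth$injected_rpm_on
scenario_config <- function(amplitude,
                            period,
                            n_cycles = 30L,
                            sampling_rate = 10000,
                            gate_open_phase = 0.40,
                            gate_close_phase = 0.60,
                            rpm_on_latency_mean = 104.20,
                            rpm_on_latency_sd = 13.64,
                            rpm_off_latency_mean = 113.60,
                            rpm_off_latency_sd = 14.98,
                            cyc_on_latency_mean = 108.29,
                            cyc_on_latency_sd = 0.85,
                            cyc_off_latency_mean = 1.20,
                            cyc_off_latency_sd = 0.04,
                            trigger_high_level = 12.0,
                            trigger_rise_time = 0.2,
                            beam_step_level = 0.100,
                            beam_rise_time = 0.2,
                            noise_motion_sd = 0.15,
                            powerline_freq = 50,
                            powerline_amplitude = 0.1,
                            spike_rate = 0.5,
                            noise_trigger_sd = 0.02,
                            noise_beam_sd = 0.002,
                            seed = NULL) {
  check_scalar(amplitude, "amplitude", lower = 0, strict_lower = TRUE)
  check_scalar(period, "period", lower = 0, strict_lower = TRUE)
  check_scalar(n_cycles, "n_cycles", lower = 1)
  if (n_cycles != round(n_cycles))
    gatelat_abort("field 'n_cycles' must be a whole number", "config")
  check_scalar(sampling_rate, "sampling_rate", lower = 1000)
  check_scalar(gate_open_phase, "gate_open_phase", lower = 0, upper = 1,
               strict_upper = TRUE)
  check_scalar(gate_close_phase, "gate_close_phase", lower = 0, upper = 1,
               strict_lower = TRUE)
  if (gate_open_phase >= gate_close_phase)
    gatelat_abort("field 'gate_open_phase' must be below 'gate_close_phase'",
                  "config")
  for (f in c("rpm_on_latency_mean", "rpm_off_latency_mean",
              "cyc_on_latency_mean", "cyc_off_latency_mean"))
    check_scalar(get(f), f, lower = 0)
  for (f in c("rpm_on_latency_sd", "rpm_off_latency_sd",
              "cyc_on_latency_sd", "cyc_off_latency_sd",
              "noise_motion_sd", "powerline_amplitude", "spike_rate",
              "noise_trigger_sd", "noise_beam_sd"))
    check_scalar(get(f), f, lower = 0)
  check_scalar(trigger_high_level, "trigger_high_level", lower = 0,
               strict_lower = TRUE)
  check_scalar(beam_step_level, "beam_step_level", lower = 0,
               strict_lower = TRUE)
  check_scalar(trigger_rise_time, "trigger_rise_time", lower = 0)
  check_scalar(beam_rise_time, "beam_rise_time", lower = 0)
  check_scalar(powerline_freq, "powerline_freq", lower = 0,
               strict_lower = TRUE)
  if (!is.null(seed)) {
    check_scalar(seed, "seed")
    seed <- as.integer(seed)
  }

  structure(list(
    amplitude = amplitude, period = period, n_cycles = as.integer(n_cycles),
    sampling_rate = sampling_rate,
    gate_open_phase = gate_open_phase, gate_close_phase = gate_close_phase,
    rpm_on_latency_mean = rpm_on_latency_mean,
    rpm_on_latency_sd = rpm_on_latency_sd,
    rpm_off_latency_mean = rpm_off_latency_mean,
    rpm_off_latency_sd = rpm_off_latency_sd,
    cyc_on_latency_mean = cyc_on_latency_mean,
    cyc_on_latency_sd = cyc_on_latency_sd,
    cyc_off_latency_mean = cyc_off_latency_mean,
    cyc_off_latency_sd = cyc_off_latency_sd,
    trigger_high_level = trigger_high_level,
    trigger_rise_time = trigger_rise_time,
    beam_step_level = beam_step_level,
    beam_rise_time = beam_rise_time,
    noise_motion_sd = noise_motion_sd,
    powerline_freq = powerline_freq,
    powerline_amplitude = powerline_amplitude,
    spike_rate = spike_rate,
    noise_trigger_sd = noise_trigger_sd,
    noise_beam_sd = noise_beam_sd,
    seed = seed
  ), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> %.3g mm p-p, %.3g s period, %d cycles @ %g Hz\n",
              x$amplitude, x$period, x$n_cycles, x$sampling_rate))
  cat(sprintf("  gate %.0f%%-%.0f%%; gating ON/OFF %.2f/%.2f ms; cyclotron ON/OFF %.2f/%.2f ms\n",
              100 * x$gate_open_phase, 100 * x$gate_close_phase,
              x$rpm_on_latency_mean, x$rpm_off_latency_mean,
              x$cyc_on_latency_mean, x$cyc_off_latency_mean))
  invisible(x)
}

# time axis with half-period padding at both ends so every analyzed peak is
# interior; motion peaks sit at t = 0, period, ..., n_cycles * period
session_time_axis <- function(config) {
  n <- round((config$n_cycles + 1L) * config$period * config$sampling_rate) + 1L
  -config$period / 2 + (seq_len(n) - 1L) / config$sampling_rate
}

# noiseless surrogate trace: peak-to-peak `amplitude`, peaks at multiples of
# the period, trough midway between peaks
motion_waveform <- function(t, amplitude, period) {
  (amplitude / 2) * (1 + cos(2 * pi * t / period))
}

# motion channel including noise terms; assumes the RNG is already positioned
motion_with_noise <- function(t, config) {
  x <- motion_waveform(t, config$amplitude, config$period)
  if (config$noise_motion_sd > 0)
    x <- x + stats::rnorm(length(t), sd = config$noise_motion_sd)
  if (config$powerline_amplitude > 0)
    x <- x + config$powerline_amplitude *
      sin(2 * pi * config$powerline_freq * t)
  if (config$spike_rate > 0 && config$noise_motion_sd > 0) {
    duration <- t[length(t)] - t[1]
    n_spikes <- stats::rpois(1L, config$spike_rate * duration)
    if (n_spikes > 0) {
      idx <- sample.int(length(t), n_spikes)
      x[idx] <- x[idx] + sample(c(-1, 1), n_spikes, replace = TRUE) *
        5 * config$noise_motion_sd
    }
  }
  x
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate the motion channel alone
#'
#' Generates the surrogate displacement trace for a scenario: a raised cosine
#' with peak-to-peak amplitude `config$amplitude` and peaks at integer
#' multiples of the period, plus Gaussian sensor noise, a mains-frequency
#' interference sinusoid, and sparse single-sample spike artifacts. The trace
#' is padded by half a period at both ends so the first and last analyzable
#' peaks are interior to the recording.
#'
#' @param config A [scenario_config()].
#' @return Numeric vector of displacements in mm, one per sample.
#' @export
simulate_motion <- function(config) {
  if (!inherits(config, "scenario_config"))
    gatelat_abort("'config' must be created by scenario_config()", "config")
  with_seed(config$seed, motion_with_noise(session_time_axis(config), config))
}

# exact inverse-CDF draw from a normal truncated at zero; sd = 0 degenerates
# to the mean
rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (1 - lo), mean, sd)
}

# piecewise-linear two-state channel: 0 before each on-ramp, `level` between
# ramps, linear transitions of `rise` seconds starting at on/off times
square_channel <- function(t, on_times, off_times, level, rise) {
  x <- numeric(length(t))
  for (k in seq_along(on_times)) {
    if (rise > 0) {
      ramp_up <- pmin(pmax((t - on_times[k]) / rise, 0), 1)
      ramp_dn <- pmin(pmax((t - off_times[k]) / rise, 0), 1)
    } else {
      ramp_up <- as.numeric(t >= on_times[k])
      ramp_dn <- as.numeric(t >= off_times[k])
    }
    x <- x + level * (ramp_up - ramp_dn)
  }
  x
}

#' Simulate a complete three-channel gating session
#'
#' Produces a synchronized recording (motion, trigger, beam channels) together
#' with its ground truth. Per cycle, gating-system and treatment-system
#' latencies are drawn independently from zero-truncated normal distributions;
#' the trigger channel ramps 0 to `trigger_high_level` starting at the true
#' trigger-on time, and the beam channel steps to `beam_step_level` after the
#' additional treatment-system delay, only while the trigger intent is on.
#'
#' By construction, for every cycle
#' `true_beam_on - true_gate_open = injected_rpm_on + injected_cyc_on`
#' exactly (and analogously for the off transition), which is the additive
#' decomposition the analysis pipeline is meant to recover.
#'
#' @param config A [scenario_config()].
#' @return A list with class `gating_session`:
#'   \describe{
#'     \item{recording}{a `gating_recording` (see [read_recording()] for the
#'       on-disk form): `time` (s), `motion` (mm), `trigger` (V), `beam` (V),
#'       `sampling_rate`, `metadata`.}
#'     \item{truth}{data frame with one row per cycle: `cycle`,
#'       `true_peak_time`, `true_gate_open_time`, `true_gate_close_time`,
#'       `true_trigger_on`, `true_trigger_off`, `true_beam_on`,
#'       `true_beam_off` (s), and `injected_rpm_on`, `injected_rpm_off`,
#'       `injected_cyc_on`, `injected_cyc_off` (ms).}
#'   }
#' @export
simulate_session <- function(config) {
  if (!inherits(config, "scenario_config"))
    gatelat_abort("'config' must be created by scenario_config()", "config")

  gate_len <- (config$gate_close_phase - config$gate_open_phase) *
    config$period
  min_len <- (config$trigger_rise_time + config$beam_rise_time) / 1000 +
    2 / config$sampling_rate
  if (gate_len < min_len)
    gatelat_abort(sprintf(
      "gating window (%.4f s) shorter than transition rise times plus two samples (%.4f s)",
      gate_len, min_len), "infeasible_scenario")

  with_seed(config$seed, {
    t <- session_time_axis(config)
    motion <- motion_with_noise(t, config)

    n <- config$n_cycles
    peak_times <- (seq_len(n) - 1L) * config$period
    gate_open <- peak_times + config$gate_open_phase * config$period
    gate_close <- peak_times + config$gate_close_phase * config$period

    rpm_on <- rtruncnorm0(n, config$rpm_on_latency_mean,
                          config$rpm_on_latency_sd)
    rpm_off <- rtruncnorm0(n, config$rpm_off_latency_mean,
                           config$rpm_off_latency_sd)
    cyc_on <- rtruncnorm0(n, config$cyc_on_latency_mean,
                          config$cyc_on_latency_sd)
    cyc_off <- rtruncnorm0(n, config$cyc_off_latency_mean,
                           config$cyc_off_latency_sd)

    trig_on <- gate_open + rpm_on / 1000
    trig_off <- gate_close + rpm_off / 1000
    beam_on <- trig_on + cyc_on / 1000
    beam_off <- trig_off + cyc_off / 1000
    # beam fires only while the trigger intent is on; a cycle whose beam-on
    # would land after beam-off produces no beam pulse
    fires <- beam_on < beam_off

    trigger <- square_channel(t, trig_on, trig_off,
                              config$trigger_high_level,
                              config$trigger_rise_time / 1000)
    beam <- square_channel(t, beam_on[fires], beam_off[fires],
                           config$beam_step_level,
                           config$beam_rise_time / 1000)
    if (config$noise_trigger_sd > 0)
      trigger <- trigger + stats::rnorm(length(t),
                                        sd = config$noise_trigger_sd)
    if (config$noise_beam_sd > 0)
      beam <- beam + stats::rnorm(length(t), sd = config$noise_beam_sd)

    recording <- new_recording(
      time = t, motion = motion, trigger = trigger, beam = beam,
      sampling_rate = config$sampling_rate,
      metadata = list(
        amplitude_mm = config$amplitude, period_s = config$period,
        n_cycles = config$n_cycles,
        seed = if (is.null(config$seed)) NA else config$seed))

    truth <- data.frame(
      cycle = seq_len(n),
      true_peak_time = peak_times,
      true_gate_open_time = gate_open,
      true_gate_close_time = gate_close,
      true_trigger_on = trig_on,
      true_trigger_off = trig_off,
      true_beam_on = beam_on,
      true_beam_off = beam_off,
      injected_rpm_on = rpm_on,
      injected_rpm_off = rpm_off,
      injected_cyc_on = cyc_on,
      injected_cyc_off = cyc_off,
      beam_fires = fires)

    structure(list(recording = recording, truth = truth, config = config),
              class = "gating_session")
  })
}

#' @export
print.gating_session <- function(x, ...) {
  cat(sprintf("<gating_session> %d cycles, %d samples @ %g Hz\n",
              nrow(x$truth), length(x$recording$time),
              x$recording$sampling_rate))
  invisible(x)
}

new_recording <- function(time, motion, trigger, beam, sampling_rate,
                          metadata = list()) {
  stopifnot(length(time) == length(motion),
            length(time) == length(trigger),
            length(time) == length(beam))
  structure(list(time = time, motion = motion, trigger = trigger,
                 beam = beam, sampling_rate = sampling_rate,
                 metadata = metadata),
            class = "gating_recording")
}

#' @export
print.gating_recording <- function(x, ...) {
  cat(sprintf("<gating_recording> %d samples @ %g Hz (%.2f s)\n",
              length(x$time), x$sampling_rate,
              x$time[length(x$time)] - x$time[1]))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), unlist(x$metadata),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Plot the three channels of a recording
#'
#' Stacked base-graphics traces of motion, trigger and beam against time.
#'
#' @param x A `gating_recording`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.gating_recording <- function(x, ...) {
  old <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(old))
  graphics::plot(x$time, x$motion, type = "l", xlab = "",
                 ylab = "motion (mm)", ...)
  graphics::plot(x$time, x$trigger, type = "l", xlab = "",
                 ylab = "trigger (V)", ...)
  graphics::plot(x$time, x$beam, type = "l", xlab = "time (s)",
                 ylab = "beam (V)", ...)
  invisible(x)
}
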