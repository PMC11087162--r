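# Shared scenario constructors for the suite.

# noiseless scenario: deterministic channels, constant injected latencies
quiet_config <- function(amplitude = 15, period = 3, n_cycles = 5,
                         rpm_on = 104.20, rpm_off = 113.60,
                         cyc_on = 108.29, cyc_off = 1.20, seed = 1, ...) {
  scenario_config(
    amplitude = amplitude, period = period, n_cycles = n_cycles,
    rpm_on_latency_mean = rpm_on, rpm_on_latency_sd = 0,
    rpm_off_latency_mean = rpm_off, rpm_off_latency_sd = 0,
    cyc_on_latency_mean = cyc_on, cyc_on_latency_sd = 0,
    cyc_off_latency_mean = cyc_off, cyc_off_latency_sd = 0,
    noise_motion_sd = 0, powerline_amplitude = 0, spike_rate = 0,
    noise_trigger_sd = 0, noise_beam_sd = 0, seed = seed, ...)
}

# default (noisy) scenario at reduced cycle count for fast unit tests
noisy_config <- function(amplitude = 15, period = 3, n_cycles = 10,
                         seed = 42, ...) {
  scenario_config(amplitude = amplitude, period = period,
                  n_cycles = n_cycles, seed = seed, ...)
}

# the 11 published motion scenarios (amplitude mm, period s)
scenario_grid <- function() {
  data.frame(amplitude = c(5, 5, 5, 10, 10, 10, 15, 15, 15, 20, 20),
             period = c(3, 4, 5, 3, 4, 5, 3, 4, 5, 4, 5))
}
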