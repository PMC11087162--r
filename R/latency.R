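#' Per-cycle latency decomposition
#'
#' Computes the six latencies of the gated-delivery chain for every matched
#' cycle, in milliseconds:
#' \describe{
#'   \item{tau_rpm_on}{trigger-on minus expected gate-open time: the gating
#'     system's beam-ON latency.}
#'   \item{tau_rpm_off}{trigger-off minus expected gate-close time.}
#'   \item{tau_cyc_on}{beam-on minus trigger-on: the treatment system's
#'     beam-ON latency.}
#'   \item{tau_cyc_off}{beam-off minus trigger-off.}
#'   \item{tau_total_on, tau_total_off}{component sums; computed from the
#'     components, never re-measured, so the additive decomposition holds
#'     bit-exactly for every cycle.}
#' }
#' Negative gating latencies (trigger before the gate boundary, i.e. the
#' gating system predicted the motion) are reported as-is with a warning ---
#' clamping them would hide exactly the behavior a QA check must surface.
#'
#' @param matched Data frame from [pair_gate_events()].
#' @return Data frame with one row per cycle: `cycle`, the six `tau_*`
#'   columns (ms), and `complete`. Incomplete cycles carry `NA` latencies.
#' @export
compute_latencies <- function(matched) {
  need <- c("cycle", "gate_open_time", "gate_close_time", "trigger_on",
            "trigger_off", "beam_on", "beam_off", "complete")
  if (!all(need %in% names(matched)))
    gatelat_abort("'matched' must come from pair_gate_events()", "config")

  tau_rpm_on <- (matched$trigger_on - matched$gate_open_time) * 1000
  tau_rpm_off <- (matched$trigger_off - matched$gate_close_time) * 1000
  tau_cyc_on <- (matched$beam_on - matched$trigger_on) * 1000
  tau_cyc_off <- (matched$beam_off - matched$trigger_off) * 1000

  neg <- sum(tau_rpm_on < 0 | tau_rpm_off < 0, na.rm = TRUE)
  if (neg > 0)
    gatelat_warn(sprintf(
      "%d cycle(s) with negative gating latency (early trigger)", neg),
      "negative_latency")

  data.frame(cycle = matched$cycle,
             tau_rpm_on = tau_rpm_on,
             tau_rpm_off = tau_rpm_off,
             tau_cyc_on = tau_cyc_on,
             tau_cyc_off = tau_cyc_off,
             tau_total_on = tau_rpm_on + tau_cyc_on,
             tau_total_off = tau_rpm_off + tau_cyc_off,
             complete = matched$complete)
}

#' Run the full latency pipeline on a recording
#'
#' Composition of the four analysis stages: motion denoising
#' ([preprocess_motion()]), cycle localization ([locate_cycles()]), edge
#' timestamping ([detect_edges()]) on the trigger and beam channels,
#' event-to-cycle matching ([pair_gate_events()]) and the latency arithmetic
#' ([compute_latencies()]). Stage failures are re-raised with the stage name
#' prefixed.
#'
#' @param recording A `gating_recording`.
#' @param filter A [filter_spec()].
#' @param gate_open_phase,gate_close_phase Gating window phases.
#' @param threshold_fraction Peak-region threshold fraction.
#' @param fit_order Polynomial order for peak fitting.
#' @param edge_low,edge_high Hysteresis fractions for edge detection.
#' @param debounce_ms Edge debounce window, ms.
#' @param plausible_period Period plausibility band, s.
#' @return An object of class `gating_analysis`: list with `latencies`
#'   (per-cycle data frame), `cycles`, `trigger_edges`, `beam_edges`, and
#'   `provenance` (effective settings plus discarded-cycle counts).
#' @export
recover_from_session <- function(recording,
                                 filter = filter_spec(),
                                 gate_open_phase = 0.40,
                                 gate_close_phase = 0.60,
                                 threshold_fraction = 0.9,
                                 fit_order = 2L,
                                 edge_low = 0.2,
                                 edge_high = 0.8,
                                 debounce_ms = 5,
                                 plausible_period = c(1, 10)) {
  if (!inherits(recording, "gating_recording"))
    gatelat_abort("'recording' must be a gating_recording", "config")
  stage <- function(name, expr) {
    withCallingHandlers(expr, gatelat_error = function(e) {
      gatelat_abort(sprintf("[%s] %s", name, conditionMessage(e)),
                    "pipeline")
    })
  }
  pre <- stage("preprocess", preprocess_motion(recording, filter))
  cycles <- stage("phases", locate_cycles(
    pre, threshold_fraction, fit_order,
    gate_open_phase, gate_close_phase, plausible_period))
  trig <- stage("edges", detect_edges(
    recording$trigger, recording$time, edge_low, edge_high, debounce_ms))
  beam <- stage("edges", detect_edges(
    recording$beam, recording$time, edge_low, edge_high, debounce_ms))
  matched <- stage("edges", pair_gate_events(cycles, trig, beam))
  lat <- stage("latency", compute_latencies(matched))

  structure(list(
    latencies = lat,
    cycles = matched,
    trigger_edges = trig,
    beam_edges = beam,
    provenance = list(
      notch_freq = filter$notch_freq, notch_q = filter$notch_q,
      median_window = filter$median_window,
      zero_phase = filter$zero_phase,
      gate_open_phase = gate_open_phase,
      gate_close_phase = gate_close_phase,
      threshold_fraction = threshold_fraction,
      fit_order = fit_order,
      edge_low = edge_low, edge_high = edge_high,
      debounce_ms = debounce_ms,
      n_cycles_found = nrow(lat),
      n_cycles_complete = sum(lat$complete),
      n_cycles_discarded = sum(!lat$complete))
  ), class = "gating_analysis")
}

#' @export
print.gating_analysis <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("<gating_analysis> %d cycles (%d complete, %d discarded)\n",
              p$n_cycles_found, p$n_cycles_complete, p$n_cycles_discarded))
  ok <- x$latencies[x$latencies$complete, ]
  if (nrow(ok) >= 2) {
    for (col in c("tau_rpm_on", "tau_rpm_off", "tau_cyc_on", "tau_cyc_off",
                  "tau_total_on", "tau_total_off"))
      cat(sprintf("  %-13s %8.2f +/- %5.2f ms\n", col,
                  mean(ok[[col]]), stats::sd(ok[[col]])))
  }
  invisible(x)
}

#' Compare recovered latencies with simulator ground truth
#'
#' Matches analysis cycles to ground-truth cycles by nearest peak time and
#' reports recovery errors for each of the four injected latencies.
#'
#' @param analysis A `gating_analysis` from [recover_from_session()].
#' @param truth Ground-truth data frame from [simulate_session()].
#' @return Data frame with one row per matched cycle: injected and recovered
#'   values (ms) plus `err_*` columns (recovered minus injected).
#' @export
validate_recovery <- function(analysis, truth) {
  cyc <- analysis$cycles
  lat <- analysis$latencies
  idx <- vapply(cyc$peak_time,
                function(p) which.min(abs(truth$true_peak_time - p)), 0L)
  out <- data.frame(
    cycle = lat$cycle,
    peak_err_ms = (cyc$peak_time - truth$true_peak_time[idx]) * 1000,
    err_rpm_on = lat$tau_rpm_on - truth$injected_rpm_on[idx],
    err_rpm_off = lat$tau_rpm_off - truth$injected_rpm_off[idx],
    err_cyc_on = lat$tau_cyc_on - truth$injected_cyc_on[idx],
    err_cyc_off = lat$tau_cyc_off - truth$injected_cyc_off[idx],
    complete = lat$complete)
  out
}
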