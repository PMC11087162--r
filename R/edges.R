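#' Timestamp state transitions on a two-state channel
#'
#' Converts a trigger or beam-detector voltage trace into a list of rising
#' and falling edge events using a Schmitt-trigger state machine: the channel
#' state switches to HIGH only when the signal reaches the high threshold
#' (default 80% of the dynamic range) and back to LOW only at the low
#' threshold (20%), so noise between the thresholds cannot generate events.
#' The reported timestamp is the linearly interpolated crossing of the 20%
#' threshold on the ascent that led to HIGH (rising) and of the 80% threshold
#' on the descent that led to LOW (falling) --- the earliest detectable point
#' of each transition.
#'
#' The dynamic range is estimated from the 5th and 95th percentiles of the
#' signal, which is robust to isolated spikes; set `percentile_range = FALSE`
#' to use the literal min/max. HIGH or LOW dwellings shorter than
#' `debounce_ms` are discarded as electrically implausible glitches.
#'
#' @param x Channel signal, V.
#' @param time Time axis, s.
#' @param low_fraction,high_fraction Hysteresis thresholds as fractions of
#'   the dynamic range (defaults 0.2 and 0.8).
#' @param debounce_ms Minimum dwell time in either state, ms; default 5.
#' @param percentile_range Use 5th/95th percentiles for baseline/top
#'   (default) instead of min/max.
#' @param snr_floor Minimum ratio of dynamic range to the channel noise
#'   estimate (median absolute successive difference); default 10.
#' @return Data frame with one row per event: `direction` ("rising" or
#'   "falling"), `timestamp` (s), `threshold_level` (V). Directions
#'   alternate; timestamps are strictly increasing.
#' @export
detect_edges <- function(x, time, low_fraction = 0.2, high_fraction = 0.8,
                         debounce_ms = 5, percentile_range = TRUE,
                         snr_floor = 10) {
  if (low_fraction <= 0 || high_fraction >= 1 ||
      low_fraction >= high_fraction)
    gatelat_abort("need 0 < low_fraction < high_fraction < 1", "config")
  if (percentile_range) {
    qs <- stats::quantile(x, c(0.05, 0.95), names = FALSE)
  } else {
    qs <- range(x)
  }
  baseline <- qs[1]
  rng <- qs[2] - qs[1]
  if (rng <= 0)
    gatelat_abort("channel has no dynamic range: no edges to detect",
                  "no_edges")
  noise <- stats::mad(diff(x)) / sqrt(2)
  if (noise > 0 && rng < snr_floor * noise)
    gatelat_abort(sprintf(
      "channel dynamic range %.3g below %g x noise estimate %.3g",
      rng, snr_floor, noise), "low_snr")

  lo_thr <- baseline + low_fraction * rng
  hi_thr <- baseline + high_fraction * rng
  if (!any(x >= hi_thr))
    gatelat_abort("no excursion reaches the high threshold", "no_edges")

  # Schmitt state machine over sample indices
  state_hi <- x >= hi_thr
  state_lo <- x <= lo_thr
  events <- list()
  state <- if (state_hi[1]) "high" else "low"   # between thresholds: low
  for (i in seq_along(x)[-1]) {
    if (state == "low" && state_hi[i]) {
      # ascent: walk back to the lo_thr crossing that led here
      j <- i
      while (j > 1L && x[j - 1L] > lo_thr) j <- j - 1L
      ts <- if (j == 1L) time[1L] else
        interp_crossing(time[j - 1L], time[j], x[j - 1L], x[j], lo_thr)
      events[[length(events) + 1L]] <-
        list(direction = "rising", timestamp = ts, threshold_level = lo_thr)
      state <- "high"
    } else if (state == "high" && state_lo[i]) {
      j <- i
      while (j > 1L && x[j - 1L] < hi_thr) j <- j - 1L
      ts <- if (j == 1L) time[1L] else
        interp_crossing(time[j - 1L], time[j], x[j - 1L], x[j], hi_thr)
      events[[length(events) + 1L]] <-
        list(direction = "falling", timestamp = ts, threshold_level = hi_thr)
      state <- "low"
    }
  }
  if (!length(events))
    gatelat_abort("no complete transitions found", "no_edges")
  ev <- data.frame(
    direction = vapply(events, `[[`, "", "direction"),
    timestamp = vapply(events, `[[`, 0, "timestamp"),
    threshold_level = vapply(events, `[[`, 0, "threshold_level"))

  debounce_edges(ev, debounce_ms / 1000)
}

interp_crossing <- function(t0, t1, y0, y1, level) {
  if (y1 == y0) return(t1)
  t0 + (level - y0) / (y1 - y0) * (t1 - t0)
}

# drop paired events bounding a dwell shorter than the debounce window;
# repeat until stable (removing a short HIGH can create a short LOW)
debounce_edges <- function(ev, min_dwell_s) {
  repeat {
    if (nrow(ev) < 2L) break
    dt <- diff(ev$timestamp)
    short <- which(dt < min_dwell_s)
    if (!length(short)) break
    k <- short[1L]
    ev <- ev[-c(k, k + 1L), , drop = FALSE]
  }
  rownames(ev) <- NULL
  ev
}

#' Match trigger and beam edges to gating cycles
#'
#' For each gating cycle, finds the first trigger rising edge inside the
#' closed window `[gate_open_time - 0.25 * period, gate_open_time +
#' 0.5 * period]`, its paired falling edge, and the first beam rising /
#' falling edge within 1 s after the corresponding trigger edge. Cycles
#' missing any of the four events are flagged incomplete and excluded from
#' statistics downstream (the count is reported, not silently dropped).
#'
#' @param cycles Data frame from [expected_gate_times()] / [locate_cycles()].
#' @param trigger_edges,beam_edges Data frames from [detect_edges()].
#' @return `cycles` with columns added: `trigger_on`, `trigger_off`,
#'   `beam_on`, `beam_off` (s; `NA` when absent) and `complete`.
#' @export
pair_gate_events <- function(cycles, trigger_edges, beam_edges) {
  for (nm in c("trigger_edges", "beam_edges")) {
    ev <- get(nm)
    if (nrow(ev) > 1L && any(ev$direction[-1] == ev$direction[-nrow(ev)]))
      gatelat_abort(sprintf("%s directions do not alternate", nm), "config")
  }
  tr_rise <- trigger_edges$timestamp[trigger_edges$direction == "rising"]
  tr_fall <- trigger_edges$timestamp[trigger_edges$direction == "falling"]
  bm_rise <- beam_edges$timestamp[beam_edges$direction == "rising"]
  bm_fall <- beam_edges$timestamp[beam_edges$direction == "falling"]

  n <- nrow(cycles)
  out <- cbind(cycles,
               trigger_on = NA_real_, trigger_off = NA_real_,
               beam_on = NA_real_, beam_off = NA_real_)
  win_lo <- cycles$gate_open_time - 0.25 * cycles$cycle_period
  win_hi <- cycles$gate_open_time + 0.50 * cycles$cycle_period
  # overlapping candidate windows make the per-cycle association ambiguous
  if (n > 1L && any(win_hi[-n] > win_lo[-1])) {
    bad <- which(win_hi[-n] > win_lo[-1])
    gatelat_abort(paste("candidate trigger windows overlap for cycles:",
                        paste(bad, collapse = ", ")), "ambiguity")
  }

  for (i in seq_len(n)) {
    cand <- tr_rise[tr_rise >= win_lo[i] & tr_rise <= win_hi[i]]
    if (!length(cand)) next
    t_on <- cand[1L]
    f <- tr_fall[tr_fall > t_on]
    t_off <- if (length(f)) f[1L] else NA_real_
    b_on_c <- bm_rise[bm_rise >= t_on & bm_rise <= t_on + 1]
    b_on <- if (length(b_on_c)) b_on_c[1L] else NA_real_
    b_off <- NA_real_
    if (!is.na(t_off)) {
      b_off_c <- bm_fall[bm_fall >= t_off & bm_fall <= t_off + 1]
      if (length(b_off_c)) b_off <- b_off_c[1L]
    }
    out$trigger_on[i] <- t_on
    out$trigger_off[i] <- t_off
    out$beam_on[i] <- b_on
    out$beam_off[i] <- b_off
  }
  out$complete <- !is.na(out$trigger_on) & !is.na(out$trigger_off) &
    !is.na(out$beam_on) & !is.na(out$beam_off)
  out
}
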