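#' Isolate motion peak regions by amplitude threshold
#'
#' A displacement threshold is set at `threshold_fraction` (default 90%) of
#' the peak-to-peak motion amplitude; maximal runs of samples at or above the
#' threshold are the peak regions used for polynomial peak fitting. Because
#' residual noise fragments the threshold crossing into many short runs, runs
#' separated by less than 10% of the typical full-peak run length (the median
#' length of near-maximal runs) are merged, and any region still shorter than
#' 10% of the longest one is dropped as an artifact. Runs that touch either
#' end of the recording are discarded (a truncated peak cannot be localized).
#'
#' @param motion Preprocessed motion signal, mm.
#' @param sampling_rate Sampling rate, Hz.
#' @param threshold_fraction Fraction of the peak-to-peak range; default 0.9.
#' @param per_cycle_range Recompute the peak-to-peak range per run rather
#'   than globally. Off by default; useful for drifting baselines.
#' @return Data frame with one row per region: `start`, `end` (half-open
#'   sample index interval `[start, end)`), `threshold` (mm).
#' @export
find_peak_regions <- function(motion, sampling_rate,
                              threshold_fraction = 0.9,
                              per_cycle_range = FALSE) {
  check_scalar(threshold_fraction, "threshold_fraction", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  n <- length(motion)
  lo <- min(motion)
  rng <- max(motion) - lo
  # relative floor: a numerically constant trace (e.g. a filtered constant)
  # carries only representation-level wiggle, not motion
  if (rng <= 1e-9 * max(abs(motion), 1))
    gatelat_abort("motion signal is constant: no cycles to analyze",
                  "no_cycles")
  threshold <- lo + threshold_fraction * rng
  above <- motion >= threshold
  if (!any(above))
    gatelat_abort("no samples above the peak threshold: no cycles found",
                  "no_cycles")

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  runs <- cbind(start = starts[keep], end = ends[keep] + 1L)  # half-open

  # merge runs separated by small gaps (noise dips inside one peak); the
  # reference length is the median of near-maximal runs, so fragmentation
  # into many short runs cannot shrink the merge window
  if (nrow(runs) > 1L) {
    lens <- runs[, "end"] - runs[, "start"]
    ref_len <- stats::median(lens[lens >= 0.5 * max(lens)])
    merged <- list(runs[1L, ])
    for (i in 2L:nrow(runs)) {
      prev <- merged[[length(merged)]]
      gap <- runs[i, "start"] - prev["end"]
      if (gap < 0.10 * ref_len) {
        prev["end"] <- runs[i, "end"]
        merged[[length(merged)]] <- prev
      } else {
        merged[[length(merged) + 1L]] <- runs[i, ]
      }
    }
    runs <- do.call(rbind, merged)
  }

  # residual short runs are threshold-grazing artifacts, not peaks
  lens <- runs[, "end"] - runs[, "start"]
  runs <- runs[lens >= 0.10 * max(lens), , drop = FALSE]

  # a run touching the boundary is an incomplete peak
  interior <- runs[, "start"] > 1L & runs[, "end"] <= n
  runs <- runs[interior, , drop = FALSE]
  if (nrow(runs) < 2L)
    gatelat_abort(sprintf(
      "only %d interior peak region(s); at least 2 full cycles required",
      nrow(runs)), "insufficient_cycles")

  thr <- rep(threshold, nrow(runs))
  if (per_cycle_range) {
    for (i in seq_len(nrow(runs))) {
      seg <- motion[runs[i, "start"]:(runs[i, "end"] - 1L)]
      thr[i] <- min(seg) + threshold_fraction * (max(seg) - min(seg))
    }
  }
  data.frame(start = runs[, "start"], end = runs[, "end"], threshold = thr)
}

# argmax of polynomial with coefficients cf (ascending powers) on [t0, t1]
poly_argmax <- function(cf, t0, t1) {
  dcf <- cf[-1] * seq_len(length(cf) - 1L)
  cand <- c(t0, t1)
  if (any(dcf != 0)) {
    rts <- polyroot(dcf)
    real <- Re(rts[abs(Im(rts)) < 1e-8])
    cand <- c(cand, real[real > t0 & real < t1])
  }
  vals <- vapply(cand, function(t) sum(cf * t^(seq_along(cf) - 1L)), 0)
  cand[which.max(vals)]
}

#' Localize one motion peak by least-squares polynomial fit
#'
#' Fits a polynomial of the given order to the samples of a peak region
#' (time recentered on the region midpoint for conditioning) and returns the
#' time at which the fitted polynomial attains its maximum over the closed
#' region interval. Fitting a smooth curve through thousands of samples
#' averages out sensor noise, which is how sub-millisecond peak timing is
#' obtained from a noisy trace.
#'
#' @param motion Motion signal, mm.
#' @param region One row of [find_peak_regions()] output (or any list with
#'   `start` and `end` sample indices, half-open).
#' @param time Time axis of the signal, s.
#' @param order Polynomial order; default 2 (a quadratic cap).
#' @return List with `peak_time` (s) and `fit_rmse` (mm).
#' @export
fit_peak <- function(motion, region, time, order = 2L) {
  i0 <- region$start
  i1 <- region$end - 1L
  npt <- i1 - i0 + 1L
  if (npt < order + 2L)
    gatelat_abort(sprintf(
      "peak region has %d samples; order-%d fit needs at least %d",
      npt, order, order + 2L), "degenerate_peak")
  tt <- time[i0:i1]
  yy <- motion[i0:i1]
  tc <- tt - mean(tt)
  X <- outer(tc, 0:order, `^`)
  cf <- stats::lm.fit(X, yy)$coefficients
  if (anyNA(cf))
    gatelat_abort("polynomial fit underdetermined on peak region",
                  "degenerate_peak")
  pk <- poly_argmax(unname(cf), tc[1], tc[npt])
  eps <- (tc[npt] - tc[1]) * 1e-9
  if (pk <= tc[1] + eps || pk >= tc[npt] - eps)
    gatelat_abort(
      "fitted maximum lies on the region boundary: not a resolvable peak",
      "degenerate_peak")
  fitted <- as.numeric(X %*% cf)
  list(peak_time = pk + mean(tt),
       fit_rmse = sqrt(mean((yy - fitted)^2)))
}

#' Expected gate open/close times from fitted peaks
#'
#' The motion peak defines phase 0 of each cycle; the cycle period is taken
#' from the spacing of adjacent fitted peaks (not from any nominal value), so
#' phase tracks the actual motion. For consecutive peaks `p[i] < p[i+1]` the
#' gate opens at `p[i] + gate_open_phase * period` and closes at
#' `p[i] + gate_close_phase * period`.
#'
#' @param peak_times Strictly increasing fitted peak times, s.
#' @param gate_open_phase,gate_close_phase Gating window phase fractions
#'   (defaults 0.40 and 0.60).
#' @param plausible_period Length-2 numeric; cycles whose measured period
#'   falls outside this band (s) are flagged with a warning.
#' @return Data frame with one row per cycle: `cycle`, `peak_time`,
#'   `cycle_period`, `gate_open_time`, `gate_close_time`, `plausible`.
#' @export
expected_gate_times <- function(peak_times, gate_open_phase = 0.40,
                                gate_close_phase = 0.60,
                                plausible_period = c(1, 10)) {
  if (length(peak_times) < 2L)
    gatelat_abort("need at least 2 peaks to define a cycle",
                  "insufficient_cycles")
  if (any(diff(peak_times) <= 0))
    gatelat_abort("peak times must be strictly increasing", "config")
  if (gate_open_phase >= gate_close_phase)
    gatelat_abort("gate_open_phase must be below gate_close_phase", "config")

  p <- peak_times[-length(peak_times)]
  period <- diff(peak_times)
  plausible <- period >= plausible_period[1] & period <= plausible_period[2]
  if (!all(plausible))
    gatelat_warn(sprintf(
      "%d cycle(s) with period outside [%g, %g] s flagged implausible",
      sum(!plausible), plausible_period[1], plausible_period[2]),
      "implausible_period")

  data.frame(cycle = seq_along(p),
             peak_time = p,
             cycle_period = period,
             gate_open_time = p + gate_open_phase * period,
             gate_close_time = p + gate_close_phase * period,
             plausible = plausible)
}

#' Locate all gating cycles in a preprocessed recording
#'
#' Convenience composition: peak regions, per-region polynomial fits, then
#' expected gate times.
#'
#' @param recording A (preprocessed) `gating_recording`.
#' @param threshold_fraction Peak-region threshold fraction.
#' @param order Polynomial fit order.
#' @param gate_open_phase,gate_close_phase Gating window phases.
#' @param plausible_period Plausibility band for cycle periods, s.
#' @return As [expected_gate_times()], with `fit_rmse` (mm) added.
#' @export
locate_cycles <- function(recording, threshold_fraction = 0.9, order = 2L,
                          gate_open_phase = 0.40, gate_close_phase = 0.60,
                          plausible_period = c(1, 10)) {
  regions <- find_peak_regions(recording$motion, recording$sampling_rate,
                               threshold_fraction)
  fits <- lapply(seq_len(nrow(regions)), function(i)
    fit_peak(recording$motion, regions[i, ], recording$time, order))
  peaks <- vapply(fits, `[[`, 0, "peak_time")
  rmse <- vapply(fits, `[[`, 0, "fit_rmse")
  cycles <- expected_gate_times(peaks, gate_open_phase, gate_close_phase,
                                plausible_period)
  cycles$fit_rmse <- rmse[-length(rmse)]
  cycles
}
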