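#' Filter settings for motion-channel denoising
#'
#' @param notch_freq Center frequency of the IIR notch, Hz (mains frequency;
#'   default 50).
#' @param notch_q Quality factor of the notch (center frequency divided by
#'   -3 dB bandwidth).
#' @param median_window Width of the moving median, in samples; must be odd.
#' @param zero_phase Apply the notch forward and backward so it adds no group
#'   delay. Turning this off leaves a causal single pass (not recommended for
#'   latency work; retained for inspecting the raw filter).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(notch_freq = 50, notch_q = 30,
                        median_window = 11L, zero_phase = TRUE) {
  check_scalar(notch_freq, "notch_freq", lower = 0, strict_lower = TRUE)
  check_scalar(notch_q, "notch_q", lower = 0, strict_lower = TRUE)
  check_scalar(median_window, "median_window", lower = 3)
  if (median_window %% 2 == 0)
    gatelat_abort("field 'median_window' must be odd", "config")
  structure(list(notch_freq = notch_freq, notch_q = notch_q,
                 median_window = as.integer(median_window),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

# biquad notch coefficients (list with b, a) for center f0 at rate fs
notch_coefficients <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  list(b = c(1, -2 * cos(w0), 1) / (1 + alpha),
       a = c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha)))
}

# point-symmetric (odd) reflection: continuous in value and slope at the
# junctions, so the filter transient a plain mirror reflection would ring
# off the end kinks is not excited; constants and monotone ramps extend
# exactly
reflect_pad <- function(x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  if (pad <= 0L) return(list(x = x, pad = 0L))
  left <- 2 * x[1L] - x[(pad + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - pad)]
  list(x = c(left, x, right), pad = pad)
}

#' Notch-filter a signal
#'
#' Second-order IIR notch (biquad) at `spec$notch_freq`, applied forward and
#' backward ([signal::filtfilt()]) so the net phase response is zero --- a
#' causal pass would delay the motion trace and bias every latency estimate
#' by a group delay of several milliseconds. The signal is reflect-padded
#' before filtering to suppress end transients; output length equals input
#' length.
#'
#' @param x Numeric signal.
#' @param sampling_rate Sampling rate, Hz.
#' @param spec A [filter_spec()].
#' @return Filtered signal, same length as `x`.
#' @export
notch_filter <- function(x, sampling_rate, spec = filter_spec()) {
  if (spec$notch_freq >= sampling_rate / 2)
    gatelat_abort(sprintf(
      "notch_freq (%g Hz) must be below the Nyquist frequency (%g Hz)",
      spec$notch_freq, sampling_rate / 2), "config")
  if (length(x) < 12L)
    gatelat_abort("signal too short to filter (need > 3x filter order)",
                  "config")
  co <- notch_coefficients(spec$notch_freq, sampling_rate, spec$notch_q)
  # remove the mean so the zero-state filter start-up sees no DC step, and
  # pad by ~3 notch time constants so the IIR transient dies inside the pad
  mu <- mean(x)
  pad <- ceiling(3 * spec$notch_q / spec$notch_freq * sampling_rate)
  p <- reflect_pad(x - mu, pad)
  y <- if (spec$zero_phase) {
    signal::filtfilt(signal::Arma(b = co$b, a = co$a), p$x)
  } else {
    as.numeric(signal::filter(signal::Arma(b = co$b, a = co$a), p$x))
  }
  y[(p$pad + 1L):(p$pad + length(x))] + mu
}

#' Moving median filter
#'
#' Centered running median with point-symmetric edge padding; removes
#' single-sample
#' spike artifacts without smearing edges or shifting peaks. Output length
#' equals input length.
#'
#' @param x Numeric signal.
#' @param window Odd window width in samples.
#' @return Filtered signal, same length as `x`.
#' @export
moving_median <- function(x, window = 11L) {
  if (window %% 2 == 0)
    gatelat_abort("'window' must be odd", "config")
  if (window > length(x))
    gatelat_abort("'window' exceeds signal length", "config")
  if (window < 3L) return(x)
  p <- reflect_pad(x, (window - 1L) %/% 2L)
  y <- stats::runmed(p$x, window, endrule = "keep")
  as.numeric(y[(p$pad + 1L):(p$pad + length(x))])
}

#' Denoise the motion channel of a recording
#'
#' Applies the notch filter then the moving median to the motion channel
#' only; the trigger and beam channels carry clean square transitions and
#' are analyzed raw.
#'
#' @param recording A `gating_recording`.
#' @param spec A [filter_spec()].
#' @return The recording with its `motion` channel filtered.
#' @export
preprocess_motion <- function(recording, spec = filter_spec()) {
  if (!inherits(recording, "gating_recording"))
    gatelat_abort("'recording' must be a gating_recording", "config")
  recording$motion <- moving_median(
    notch_filter(recording$motion, recording$sampling_rate, spec),
    spec$median_window)
  recording$metadata$preprocessed <- sprintf(
    "notch %g Hz Q=%g%s; median %d",
    spec$notch_freq, spec$notch_q,
    if (spec$zero_phase) " zero-phase" else "", spec$median_window)
  recording
}
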