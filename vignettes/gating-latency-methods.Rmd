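---
title: "Measuring beam delivery latency in gated radiotherapy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring beam delivery latency in gated radiotherapy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatelat)
```

## The measurement problem

In respiratory-gated radiotherapy the beam is only permitted while a
breathing surrogate sits inside a predefined gating window — here a phase
window, 40%–60% of the breathing cycle, with peak displacement defined as
phase 0%/100% so the window is centered on the trough. Two systems stand
between the surrogate crossing a window boundary and the beam actually
changing state:

1. the **gating system**, which tracks the surrogate optically and flips a
   two-state beam-permission trigger (0 V = beam off, 12 V = beam on), and
2. the **treatment system**, which must start or dump the beam when the
   trigger changes.

Each adds delay. With a synchronized three-channel recording — surrogate
displacement, trigger voltage, beam-detector voltage, all sampled at 10 kHz
— the two delays can be measured separately for every motion cycle:

* gating ON latency `tau_rpm_on = T_trigger_on − T_gate_open`,
* gating OFF latency `tau_rpm_off = T_trigger_off − T_gate_close`,
* treatment ON latency `tau_cyc_on = T_beam_on − T_trigger_on`,
* treatment OFF latency `tau_cyc_off = T_beam_off − T_trigger_off`,

and the totals are the sums `tau_total_on = tau_rpm_on + tau_cyc_on`,
`tau_total_off = tau_rpm_off + tau_cyc_off`. In `gatelat` the totals are
always *derived* from the components rather than re-measured from the beam
and motion channels directly; the two definitions are algebraically
identical, and deriving makes the additive decomposition hold bit-exactly
per cycle, which the test suite asserts.

The gate boundary times `T_gate_open` / `T_gate_close` are not observable
directly; they are *expected* times computed from the motion channel, which
is why the motion processing below matters.

## Pipeline

### Motion denoising

Only the motion channel is filtered; the trigger and beam channels carry
clean near-square transitions and are analyzed raw.

* **Notch filter** (`notch_filter()`): a second-order IIR biquad at the
  mains frequency (default 50 Hz, Q = 30), applied forward and backward
  (`signal::filtfilt`). A causal pass would add group delay of several
  milliseconds in the breathing band and bias every latency; the
  forward-backward pass has exactly zero net phase, at the cost of being
  offline-only — acceptable, since analysis is retrospective. At the
  defaults the squared magnitude response leaves less than 5% of a 50 Hz
  tone and attenuates a 0.3 Hz breathing tone by under 0.1%.
* **Moving median** (`moving_median()`, default window 11 samples =
  1.1 ms): removes single-sample spike artifacts without shifting peaks.

Both filters pad the signal with a *point-symmetric* (odd) reflection of
its ends: that extension is continuous in value and slope, so the IIR
transient that a plain mirror reflection would ring off the end kinks is
not excited, constants pass through exactly, and monotone ramps are
unchanged. The notch additionally removes the signal mean before filtering
(the notch has unit DC gain, so this is gain-neutral) to avoid a DC
start-up step in the zero-state filter. The analysis discards half a
motion period at each end of the recording anyway, so edge behavior never
reaches the statistics.

The published description of the method names a notch and a moving median
but neither the notch frequency, its Q, nor the median window; all three
are parameters of `filter_spec()` with the defaults above.

### Cycle phase localization

`find_peak_regions()` thresholds the motion at 90% of its peak-to-peak
amplitude (computed globally over the recording; a per-region option exists
for drifting baselines) and keeps maximal runs above the threshold. For an
ideal sinusoid a fraction `acos(0.8)/pi ≈ 0.205` of each period lies above
that threshold, so each region is ~0.6 s at a 3 s period. Two practical
rules harden this against noise:

* Residual noise fragments the threshold crossing into many short runs, so
  runs separated by less than 10% of the *typical full-peak run length*
  (median of runs at least half as long as the longest) are merged, and
  any region still shorter than 10% of the longest is dropped as a
  threshold-grazing artifact. Referencing the merge window to near-maximal
  runs rather than the plain median is deliberate: under fragmentation the
  plain median collapses to a few samples and no merging would occur.
* Runs touching either recording boundary are discarded — a truncated
  peak cannot be localized.

`fit_peak()` then fits each region with a least-squares polynomial
(default order 2; order 4 is tested too) on a recentered time axis and
takes the argmax of the fitted curve over the closed region interval,
requiring it to be interior. Fitting thousands of samples averages the
sensor noise down to sub-millisecond peak timing; on simulated sessions
with the default noise model the maximum peak-time error over 30 cycles is
about 1 ms, comfortably inside the 3 ms agreement reported for the original
software against manual readings.

`expected_gate_times()` converts consecutive fitted peaks into cycles:
each cycle's period is the spacing of its bounding peaks (the nominal
scenario period is never used — it is unknown for real recordings), and
the gate opens/closes at 40%/60% of that per-cycle period after the
preceding peak. For ideal sinusoids referencing the window to the
preceding or the following peak is equivalent; the preceding-peak
convention is fixed here. Cycles with periods outside a plausibility band
(default 1–10 s) are flagged with a warning rather than dropped.

### Edge timestamping

`detect_edges()` runs a Schmitt-trigger state machine over the trigger and
beam channels: the state becomes HIGH only at or above the high threshold
(80% of the dynamic range) and LOW only at or below the low threshold
(20%), so noise between the thresholds cannot toggle the state. The
reported timestamps are sub-sample linear interpolations: the 20% crossing
of the ascent that led to HIGH (rising) and the 80% crossing of the
descent that led to LOW (falling) — the earliest detectable point of each
transition. For near-square 12 V and 100 mV signals with sub-millisecond
rise times, the alternative reading of "20%/80%" differs by far less than
the reported precision. The dynamic range is estimated from the 5th/95th
percentiles (robust to spikes; literal min/max available behind a flag),
and dwellings shorter than 5 ms are debounced away — no physical trigger
or beam event in this system is that short.

`pair_gate_events()` associates edges to cycles: the first trigger rising
edge in the closed window `[gate_open − 0.25 period, gate_open +
0.5 period]`, its following falling edge, and the first beam edges within
1 s of the corresponding trigger edges. Cycles missing any event are
flagged incomplete, counted, and excluded from statistics.

Negative gating latencies (trigger before the gate boundary — predictive
triggering) are reported with a warning, never clamped: they are exactly
what a QA reviewer needs to see.

### Reporting

`summarize_scenario()` gives mean and sample (n−1) standard deviation per
latency over complete cycles; the published work does not state the sd
denominator, and at n = 30 the difference is ~2%. `grand_summary()`
averages scenario means without weighting — verified to reproduce the
published grand-mean row to its printed precision — and reports, by
default, the standard deviation of the pooled per-cycle values (exact when
per-cycle data are supplied, reconstructed from per-scenario moments
otherwise; a mean-of-sds option exists). Reconstructed from the *printed,
rounded* per-scenario rows, the pooled sd comes out 13.51 ms for the
gating-ON column against a published 14 ms-scale value of 13.64 — the
printed rows do not carry enough precision to settle which convention the
original analysis used, so the choice is documented rather than asserted.
Report tables round half-away-from-zero to 2 decimals for display; CSV
output keeps 4 decimals.

## The synthetic session generator

No public recordings exist for this kind of platform, so `gatelat` ships a
generator (`simulate_session()`) whose defaults are the study conditions of
the published measurement campaign:

* sinusoidal vertical motion, peak-to-peak amplitude 5–20 mm, period
  3–5 s, 30 cycles per scenario, 10 kHz sampling (11 scenarios: the
  5 mm / 3 s … 20 mm / 5 s grid in `reference_scenarios()`);
* "amplitude" is taken as peak-to-peak surrogate displacement (the source
  description does not fix this; peak-to-peak is the reading consistent
  with a 90%-of-peak-to-peak threshold);
* a 0 V / 12 V trigger and a 100 mV beam step, with linear transition
  ramps of 0.2 ms so threshold interpolation is actually exercised (the
  hardware shows near-square signals but no rise time is stated);
* per-cycle latencies drawn independently from normal distributions
  truncated at zero (only mean ± sd are published; truncation prevents
  unphysical negative delays), defaulting to the published grand means:
  gating ON/OFF 104.20 ± 13.64 / 113.60 ± 14.98 ms, treatment ON/OFF
  108.29 ± 0.85 / 1.20 ± 0.04 ms;
* measurement noise: Gaussian motion noise (0.15 mm sd), 50 Hz mains
  interference (0.1 mm), Poisson spike artifacts (0.5/s, amplitude 5
  motion-noise sds — the artifact the median filter exists for), and
  Gaussian channel noise on trigger (20 mV) and beam (2 mV). These levels
  are not published; they were chosen once as representative of a string
  potentiometer and photodiode on a 14-bit DAQ and kept fixed.

The generator does **not** model the gating camera's 25 fps frame
quantization separately — its effect is part of the end-to-end gating
latency being drawn — nor beam pulse microstructure (the beam channel is a
two-state envelope, as a photodiode sees it), nor patient-like irregular
breathing. Passing recovery tests on this generator therefore demonstrates
that the *analysis* is unbiased at realistic noise levels, not that any
particular hardware meets a tolerance.

Each simulated cycle records its ground truth, so the pipeline can be
validated end to end: on noiseless sessions across all 11 scenarios every
injected latency is recovered within 0.5 ms; with the default noise model,
within 3 ms (both asserted in the test suite). The residual noiseless bias
is the 20%-of-rise-time offset (0.04 ms at the defaults) that the
interpolated threshold timestamp carries relative to the ramp start; it
cancels entirely in the treatment-system latencies, which are differences
of two such timestamps.

## Numerical choices and degenerate inputs

* Times are stored in seconds internally; latencies are reported in
  milliseconds. Serialized times carry 6 decimals (0.1 ms at 10 kHz is
  exact).
* A motion trace whose range is at the floating-point level is treated as
  constant (no-cycles error) rather than fit.
* A fitted peak on a region boundary raises a degenerate-peak error rather
  than returning an extrapolation.
* Peak localization is invariant to positive gain and offset of the motion
  channel; edge timestamps are invariant to channel gain — both asserted
  as properties.
* Problem sizes in the test suite: unit tests run 2–15-cycle sessions;
  the recovery sweep runs all 11 scenarios at the full 30 cycles,
  noiseless and noisy (about two minutes in total).

## Known limitations

* Sinusoidal QA traces only: no phase model for irregular breathing (no
  Hilbert transform or phase unwrapping), so the package is for platform
  QA, not patient-trace analysis.
* The gating window is phase-based; displacement-gating would change
  `expected_gate_times()` only, but is not implemented.
* No dosimetric interpretation of latency and no pass/fail policy engine;
  tolerance comparison is left to the user's protocol.
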