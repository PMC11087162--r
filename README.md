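# gatelat

Beam delivery latency analysis for respiratory-gated radiotherapy.

In gated treatment, the beam is only permitted while a breathing surrogate
sits inside a gating window (here the 40%–60% phase interval of the cycle,
with peak displacement as phase 0). Two systems add delay between the
surrogate crossing a window boundary and the beam actually switching: the
gating system (surrogate tracked optically → a 0 V / 12 V beam-permission
trigger) and the treatment system (trigger → beam). From a synchronized
three-channel recording — surrogate motion (mm), trigger voltage (V), and a
beam-detector voltage (V), nominally at 10 kHz — `gatelat` measures both
delays separately for every motion cycle:

    tau_rpm_on  = T_trigger_on  - T_gate_open      (gating system, beam ON)
    tau_rpm_off = T_trigger_off - T_gate_close     (gating system, beam OFF)
    tau_cyc_on  = T_beam_on     - T_trigger_on     (treatment system, beam ON)
    tau_cyc_off = T_beam_off    - T_trigger_off    (treatment system, beam OFF)
    tau_total_on  = tau_rpm_on  + tau_cyc_on
    tau_total_off = tau_rpm_off + tau_cyc_off

The pipeline: zero-phase 50 Hz notch + moving-median denoising of the
motion channel → motion peaks localized by least-squares polynomial fits on
90%-amplitude peak regions → expected gate open/close times from per-cycle
periods → Schmitt-style 20%/80% edge timestamping with sub-sample
interpolation on the trigger and beam channels → per-cycle latency table →
QA report with per-scenario and grand summaries.

A synthetic session generator (`simulate_session()`) with known per-cycle
ground truth emulates the full measurement platform (sinusoidal phantom
motion, trigger, ~100 mV beam step, realistic noise and injected latency
distributions), so the entire pipeline is validated end to end without
hardware.

## Worked example

```r
library(gatelat)

cfg <- scenario_config(amplitude = 15, period = 3, n_cycles = 30, seed = 42)
ses <- simulate_session(cfg)          # recording + ground truth
ana <- recover_from_session(ses$recording)
print(ana)
#> <gating_analysis> 30 cycles (30 complete, 0 discarded)
#>   tau_rpm_on      105.86 +/- 12.59 ms
#>   tau_rpm_off     114.00 +/- 13.27 ms
#>   tau_cyc_on      108.36 +/-  0.70 ms
#>   tau_cyc_off       1.20 +/-  0.03 ms
#>   tau_total_on    214.21 +/- 12.77 ms
#>   tau_total_off   115.20 +/- 13.27 ms
```

Reading: over 30 simulated cycles the gating system took ~106 ms to raise
the trigger after the surrogate entered the window and ~114 ms to drop it
after exit; the treatment system needed a further ~108 ms to deliver beam
after trigger-on but only ~1.2 ms to stop it after trigger-off. The sample
means sit within the Monte-Carlo error of the injected distributions
(gating 104.20 ± 13.64 / 113.60 ± 14.98 ms, treatment 108.29 ± 0.85 /
1.20 ± 0.04 ms), and recovery against the per-cycle ground truth is
sub-millisecond:

```r
v <- validate_recovery(ana, ses$truth)
max(abs(v$peak_err_ms))               # fitted vs true peak time
#> [1] 0.7611990
```

Scenario tables in the conventional report layout:

```r
s <- summarize_scenario(ana$latencies, amplitude = 15, period = 3)
cat(render_report(s))
#> Scenario       n   rpm_on (ms)        rpm_off (ms)       cyc_on (ms)  ...
#> 15 mm / 3 s    30  105.86 ± 12.59     114.00 ± 13.27     108.36 ± 0.70 ...
#> Mean           30  ...
```

`reference_scenarios()` ships the published 11-scenario summary table of an
RPM-gated cyclotron proton system for report arithmetic and as the source
of the simulator's default latency distributions.

A command-line wrapper (`inst/cli/gatelat`) exposes `simulate`, `analyze`,
`report` and `validate` subcommands over CSV/JSON artifacts:

```sh
Rscript inst/cli/gatelat simulate --amplitude 15 --period 3 --cycles 30 \
    --seed 7 --out rec.csv --truth truth.json
Rscript inst/cli/gatelat analyze --in rec.csv --out lat.csv
Rscript inst/cli/gatelat validate --in rec.csv --truth truth.json
```

See `vignettes/gating-latency-methods.Rmd` for the model, parameter
defaults, and design rationale.

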