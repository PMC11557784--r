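# piva

Peripheral Intravenous Analysis (PIVA) of venous pressure waveforms during
cardiopulmonary resuscitation.

## What problem this solves

During mechanical CPR, chest compressions at a fixed rate (nominally
200 min⁻¹, i.e. 3.33 Hz) drive a pressure oscillation in every
fluid-coupled venous line — including an ordinary peripheral IV. The
amplitude of that oscillation tracks venous return: it rises as
compressions begin moving blood, peaks, and declines again shortly before
return of spontaneous circulation (ROSC). Detecting that peak, and the
subsequent end-tidal CO2 surge, gives early warning of impending ROSC from
signals already present at the bedside.

This package is for physiologists and resuscitation researchers who record
multi-channel pressure/capnography time series during CPR experiments. It
provides:

* **Spectral PIVA extraction** — non-overlapping 8192-sample FFT windows
  (8 s of signal at the 1 kHz acquisition rate), single-sided amplitude
  scaling, and a dominant-frequency search restricted to a ±1 Hz band
  around the compression rate. The PIVA value of a window is the amplitude
  (mmHg) at the dominant in-band bin:

  `PIVA = (2 / N) |X_k*|`, with `k* = argmax_{k in band} |X_k|`, `N = 8192`.

* **Event detection** — PIVA peak per venous site (argmax over CPR
  windows); the etCO2 criterion (first instant the trace exceeds twice its
  lowest value during CPR); coronary perfusion pressure
  `CPP = diastolic − min(CVP)`; per-cycle systole/diastole/MAP and venous
  peak-to-trough amplitudes; quarter-segmented means over the CPR interval.

* **Timing statistics** — per-event-type `ROSC − event time` (s before
  ROSC), mean ± SE, Shapiro–Wilk screening, uncorrected Fisher's LSD
  pairwise comparisons (α = 0.05), with an optional paired
  (repeated-measures) mode.

* **A seeded synthetic recording generator** with ground truth (true peak
  times, true etCO2 doubling instant), standing in for the unreleased
  animal recordings, so the entire pipeline is testable end to end.

## Worked example

```r
library(piva)

sim <- generate_recording(sim_config(rng_seed = 1))   # 80 s, 5 channels, 1 kHz
det <- detect_events(sim$recording)                   # 8192-sample windows, no overlap
es  <- det$event_set
```

For seed 1 this prints (peak value, peak time, and time before the
annotated ROSC at 65 s):

```
tail_venous     peak  0.84 mmHg at  28.7 s (36.3 s before ROSC)
femoral_venous  peak  2.48 mmHg at  36.9 s (28.1 s before ROSC)
central_venous  peak  4.20 mmHg at  45.1 s (19.9 s before ROSC)
etCO2 doubling  baseline 18.0 mmHg, rise at 43.7 s (21.3 s before ROSC)
```

The tail-vein PIVA peak precedes the femoral and central peaks, and every
PIVA peak precedes the etCO2 surge — the published ordering. At the default
non-overlapping hop, peak times are quantized to 8.192 s windows; pass
`hop = 1024, taper = "hann"` for finer timing. An 8-subject cohort with
subject-level variability in true peak times:

```r
set.seed(2)
subjects <- lapply(1:8, function(i) {
  pk <- sort(c(20.3, 24.1, 29.9) + rnorm(3, 0, 1.5))
  cfg <- sim_config(rng_seed = i, sites = list(
    tail    = list(baseline_pressure = 13,   peak_amplitude = 1, peak_time = pk[1],
                   rise_width = 15, fall_width = 12),
    femoral = list(baseline_pressure = 14,   peak_amplitude = 3, peak_time = pk[2],
                   rise_width = 18, fall_width = 15),
    central = list(baseline_pressure = 13.5, peak_amplitude = 5, peak_time = pk[3],
                   rise_width = 20, fall_width = 30)))
  detect_events(generate_recording(cfg)$recording,
                hop = 1024, taper = "hann")$event_set
})
compare_event_timings(subjects)$comparisons
```

```
Fisher's LSD (between-group), alpha = 0.05, MSE = 2.088, df = 28
                    group     mean           se n shapiro_W    shapiro_p
    tail_venous_piva_peak 35.17600 0.4512534923 8 0.9581349 0.7921577086
 femoral_venous_piva_peak 31.20800 0.3870356204 8 0.8599491 0.1199348362
 central_venous_piva_peak 24.16800 0.8309443853 8 0.8664610 0.1391455195
               etco2_rise 21.25163 0.0002630521 8 0.6012830 0.0001645949
```

Means are seconds before ROSC: the tail PIVA peak leads (35.2 ± 0.5 s),
followed by femoral (31.2 ± 0.4 s) and central (24.2 ± 0.8 s), with the
etCO2 surge last (21.3 s) — all pairwise LSD p-values ≪ 0.05 in this
low-noise simulation. (The tiny etCO2 SE and its low Shapiro–Wilk p reflect
the generator's fixed surge time; only the venous peak times were varied.)

## Command line

```sh
piva simulate --out sim/ --seed 1                  # recording.csv + sidecar + ground_truth.json
piva analyze  --recording sim/recording.csv --sidecar sim/recording.json \
              --out analysis/                      # events.json, piva_<ch>.csv, quarters.csv
piva report   --out report/ analysis/events.json   # timing_table.csv, comparisons.json, summary.txt
```

The launcher is installed at `system.file("cli", "piva", package = "piva")`;
the same entry points are exported as `run_simulate()`, `run_analyze()`,
`run_report()` and `cli_main()`.

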