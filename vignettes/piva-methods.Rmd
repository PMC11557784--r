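---
title: "PIVA methods: windowed spectral amplitude of venous pressure during CPR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PIVA methods: windowed spectral amplitude of venous pressure during CPR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piva)
```

## The problem

During cardiopulmonary resuscitation (CPR) with a mechanical piston device,
chest compressions at a fixed rate (nominally 200 per minute in the rodent
setting this package targets, i.e. 3.33 Hz) drive a pressure oscillation that
is visible in any fluid-coupled venous line — a peripheral IV in the tail or
femoral vein as much as a central venous catheter. The amplitude of that
oscillation tracks venous return: it grows as compressions begin to move
blood, peaks, and then declines shortly before spontaneous circulation
returns (ROSC), as the recovering heart starts emptying the venous
compartment itself. Peripheral Intravenous Analysis (PIVA) quantifies this:
the amplitude of the venous pressure waveform at the compression frequency,
computed per FFT window. The package implements the full pipeline — windowed
spectral extraction, event detection (PIVA peak per site, the end-tidal CO2
"doubling" criterion), hemodynamic summaries over CPR quarters, and timing
statistics relative to ROSC — together with a synthetic recording generator,
because the animal recordings behind the published analysis are not publicly
deposited.

## The spectral estimator

Each venous channel is cut into consecutive windows of 8192 samples (8 K; at
the 1 kHz acquisition rate that is 8.192 s of signal, 8 whole seconds being
required per window) with no overlap by default. Per window:

1. the mean is subtracted, so baseline venous pressure (typically 12–15
   mmHg) does not leak into low-frequency bins;
2. the FFT is taken with a rectangular taper (no apodization) by default;
3. amplitudes are scaled single-sided, `2|X_k|/N` for interior bins, so a
   sinusoid of amplitude A at an exact bin frequency reads A (in mmHg);
4. the dominant bin is located inside a search band of ±1 Hz around the
   annotated compression rate — never globally, so the ventilation peak
   (60 breaths/min = 1 Hz) and post-ROSC cardiac activity cannot be
   selected;
5. the PIVA value for the window is the amplitude at that bin.

A Parseval identity test pins the scaling convention: for a zero-mean
window, `sum(a_k^2) * N/2` over interior bins (plus `N` times the squared DC
and Nyquist amplitudes) equals the sum of squared samples.

### Leakage: what the defaults do and do not recover

With N = 8192 at 1 kHz the bin spacing is 0.1220703 Hz and the 200/min
compression tone (3.3333 Hz) falls 0.31 bins above bin 27 (3.2959 Hz). The
dominant bin is therefore reported as 3.2959 Hz — 3.3 Hz to the printed
precision — but the rectangular-window scalloping loss at that offset is
about 15%: a constant-envelope tone of amplitude A reads ≈ 0.854 A,
with a further ±0.4% ripple depending on the tone's phase within the
window. The test suite asserts the measured value against a brute-force DFT
oracle to 1e-6 rather than pretending the loss away. Two mitigations are
built in:

* `method = "band"`: root-sum-square over the dominant bin ±1, which
  recovers ≈ 0.95 A at worst-case offset;
* `taper = "hann"` with coherent-gain (0.5) compensation, which flattens
  the phase ripple almost completely.

These matter for *relative* analyses too. With overlapping windows
(`hop < window_length`) the tone's phase differs window to window, so the
±0.4% rectangular-taper ripple becomes window-to-window jitter. Near the
envelope peak, where the true amplitude changes by well under 1% over 2 s,
that jitter — not noise — dominates peak-time error. The fine-hop
peak-recovery property (hop = window/8, peak within 2 s of truth) is
therefore exercised with the Hann taper; at the default non-overlapping hop
the rectangular taper meets its one-window-length tolerance comfortably.
This is an estimator-variant choice documented here precisely because the
original analysis does not state whether a taper was used.

## Event detection

**PIVA peak.** The published pattern is a single prominent peak followed by
decline, so the detector is an argmax over windows whose centers fall in
the CPR interval, ties to the earliest window. A steadily increasing series
(the central-venous pattern) legitimately peaks at its last window. An
optional minimum-prominence warning exists for noisy field data but is off
by default.

**etCO2 doubling.** A significant etCO2 rise is defined as an increase of
more than 100% over the first lowest value during CPR. "First lowest value"
is not operationalized in the source; the default reading here is the
running minimum — the event fires the first instant the (1 s
moving-average smoothed, by default) trace exceeds twice the lowest value
seen so far in the interval, and the reported baseline is that running
minimum. The alternative (`baseline_rule = "global"`) anchors the baseline
at the interval's global minimum first and searches after it; the two
differ when an early bump already doubles the early minimum before the
trace descends further. On noiseless traces the detector reproduces the
rule to the sample; under 0.5 mmHg noise with 1 s smoothing it recovers
the generator's truth within 1 s.

**CPP and per-cycle metrics.** Coronary perfusion pressure is diastolic
arterial pressure minus the minimal CVP over the CPR interval — a scalar
minimum, so CPP is invariant to any CVP perturbation that leaves the
minimum untouched. Per-cycle arterial systole/diastole/MAP and venous
peak-to-trough amplitudes use clock-based segmentation at the nominal rate
(fs·60/rate samples per cycle, trailing partial cycle dropped); with a
piston device the rate is crystal-stable, so trough detection would add
failure modes without benefit. Note that the quarter-table "venous
amplitude" is this time-domain peak-to-trough quantity (≈ 2× the sinusoid
amplitude), deliberately kept distinct from the FFT-derived PIVA value.

**Quarters.** To normalize CPR epochs of different lengths, each metric is
averaged within four equal-duration quarters of [CPR start, ROSC]. With
equal observation counts the quarter means average exactly to the overall
mean — an identity the tests assert.

## Timing statistics

Per subject and event type the statistic is `rosc_time − event_time` in
seconds (positive = before ROSC). Cohort descriptives are mean ± SE (SD
with n−1 denominator over √n). Normality is screened per event type with
Shapiro–Wilk, and event types are compared with the uncorrected Fisher's
LSD: one-way ANOVA pooled MSE, pairwise t with df = N − k, two-sided, no
multiplicity correction (the unprotected per-pair level is the stated
convention; a type-I simulation in the acceptance tests confirms the 5%
per-pair level within ±2%). Because every subject contributes all event
types, a paired mode (`paired = TRUE`) with a subject-blocked
repeated-measures error term and df = (n−1)(k−1) is offered; the default
remains the classical between-group LSD as named by the source methods.
Missing events give missing cells, handled per-pair complete-case.

## The synthetic generator: its world and its limits

The generator emulates exactly what the pipeline exercises, with defaults
fixed from the published scenario: 1 kHz sampling; 55 s of CPR (reported
ROSC at 54.6 ± 1.5 s); compressions at 200/min, ventilation at 60/min; a
venous compression oscillation whose amplitude follows an asymmetric
Gaussian envelope (separate rise/fall SDs — the published exemplar shows a
smooth unimodal bump; a piecewise-linear family is available); site peak
times staggered tail (20.3 s) < femoral (24.1 s) < central (29.9 s), i.e.
the CPR duration minus the reported mean pre-ROSC offsets 34.7/30.9/25.1 s;
site amplitudes 1/3/5 mmHg (order of magnitude of the published quarter
table; within-animal magnitudes are unpublished, so these are free
parameters, with envelope widths 15/12, 18/15, 20/30 s chosen once as
plausible and never revisited); a ventilation sinusoid at 10% of the
compression amplitude so spectra contain the realistic second peak the band
search must ignore; an arterial mean-pressure ramp 14.4 → 81.7 mmHg with a
10 mmHg compression-synchronous pulse; an etCO2 trace at 28 mmHg dipping to
18 early in CPR and surging logistically to 48.7 mmHg centered 33.5 s into
CPR (55 − 21.5); additive white Gaussian noise, SD 0.1 mmHg (10% of the
smallest site amplitude — no noise characterization is published). ROSC is
annotated at the moment compressions stop. Ground truth (true peak times,
true etCO2 doubling instant computed on the noiseless trace by the same
rule the detector applies, true compression frequency) is emitted alongside.

What the generator does **not** model — and hence what a green test does
not establish: cardiac-cycle morphology and its harmonics, respiratory
modulation of venous pressure beyond a pure sinusoid, compression-rate
drift, transducer artifacts (flushes, clots, movement), non-Gaussian or
correlated noise, and ventricular-fibrillation arrest physiology.
Parameter-recovery results certify the pipeline's internal consistency on
this stated world, not clinical performance.

## Numerical choices and degenerate inputs

* "8 K" window = 8192 samples (power-of-two convention); at 1 kHz the
  8.192 s window is what the literature rounds to "8 s".
* Trailing partial windows are discarded; a recording shorter than one
  window yields an empty series with a warning, not an error.
* Windows straddling CPR boundaries are retained and flagged (`in_cpr`),
  and the CLI logs them; dropping them would discard up to 16 s of a ~55 s
  epoch.
* Window timestamps are centers, for unbiased event timing.
* Dominant-frequency ties break toward the lower frequency; PIVA peak ties
  toward the earlier window.
* The etCO2 rule errors on non-positive baselines (a relative rule is
  undefined there; it flags unit/offset problems rather than guessing).
* Fisher's LSD errors on zero pooled variance; Shapiro–Wilk on constant
  vectors and n < 3.
* All serialized timestamps are seconds from the first sample; samples are
  written with 9 significant digits (configurable) and annotations at full
  precision.

## Known limitations

Offline analysis only (as the source analysis was); no real-time streaming.
With non-overlapping 8.192 s windows a ~55 s CPR epoch yields at most 6–7
windows, so peak-time resolution at the default hop is one window length;
use a finer hop (with the Hann taper) when finer timing matters. The
between-group LSD ignores the within-subject pairing of event types unless
`paired = TRUE`. No EDF/WFDB readers — interchange is CSV + JSON sidecar,
plus a tab-delimited chart-export dialect.
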