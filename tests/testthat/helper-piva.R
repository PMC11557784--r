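# Shared fixtures: all generated in code, no files.

# A pure tone packaged as a single-channel venous recording. Defaults give
# an exact-bin compression frequency for an 8192-sample window at 1 kHz
# (32 bins * 1000/8192 = 3.90625 Hz = 234.375/min), so amplitude recovery
# is exact up to float error.
tone_recording <- function(A = 5, f = 32 * 1000 / 8192, fs = 1000,
                           duration = 40, baseline = 12, phase = 0) {
  t <- (seq_len(round(duration * fs)) - 1) / fs
  x <- baseline + A * sin(2 * pi * f * t + phase)
  recording(
    samples = matrix(x, ncol = 1, dimnames = list(NULL, "venous_tone")),
    sampling_rate = fs,
    channel_kinds = c(venous_tone = "venous"),
    annotations = list(cpr_start = 0.5, rosc_time = duration,
                       nominal_compression_rate = f * 60)
  )
}

# Small, fast simulation config: short epochs, exact-bin compression rate
# available on demand.
quick_config <- function(...) {
  args <- list(
    pre_cpr_duration = 5, cpr_duration = 40, post_rosc_duration = 5,
    sites = list(
      tail = list(baseline_pressure = 13, peak_amplitude = 1,
                  peak_time = 12, rise_width = 10, fall_width = 8),
      femoral = list(baseline_pressure = 14, peak_amplitude = 3,
                     peak_time = 18, rise_width = 12, fall_width = 10),
      central = list(baseline_pressure = 13.5, peak_amplitude = 5,
                     peak_time = 24, rise_width = 14, fall_width = 20)
    ),
    etco2 = list(baseline = 28, dip_value = 18, surge_time = 25,
                 surge_value = 48.7, transition_width = 3)
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# Brute-force single-bin DFT amplitude (the independent spectral oracle):
# direct complex sum, mean-subtracted, single-sided 2|X_k|/N scaling.
dft_bin_amplitude <- function(x, k) {
  n <- length(x)
  x <- x - mean(x)
  idx <- 0:(n - 1)
  re <- sum(x * cos(2 * pi * k * idx / n))
  im <- -sum(x * sin(2 * pi * k * idx / n))
  2 * sqrt(re^2 + im^2) / n
}
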