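make_series <- function(time, value) {
  structure(data.frame(time = time, value = value,
                       frequency = NA_real_, window_start = time - 1,
                       in_cpr = TRUE),
            class = c("piva_series", "data.frame"))
}

test_that("PIVA peak detection: argmax, monotone, ties, empty interval", {
  s <- make_series(seq(2, 20, by = 2), c(1, 2, 5, 9, 7, 4, 3, 2, 1, 1))
  pk <- detect_piva_peak(s, c(0, 25))
  expect_equal(pk$time, 8)
  expect_equal(pk$value, 9)
  # monotone increasing -> last window (steadily rising central pattern)
  s2 <- make_series(1:6, 1:6)
  expect_equal(detect_piva_peak(s2, c(0, 10))$time, 6)
  # ties -> earliest
  s3 <- make_series(1:5, c(1, 4, 2, 4, 1))
  expect_equal(detect_piva_peak(s3, c(0, 10))$time, 2)
  # interval restriction
  expect_equal(detect_piva_peak(s, c(9, 25))$time, 10)
  expect_error(detect_piva_peak(s, c(100, 200)), "smaller hop")
})

test_that("etCO2 rule applied verbatim on a noiseless piecewise trace", {
  fs <- 10
  t <- seq(0, 60, by = 1 / fs)
  v <- ifelse(t < 35, 15, ifelse(t < 50, 10, 25))
  r <- detect_etco2_rise(v, fs, c(0, 60), smoothing = 0)
  expect_true(r$met)
  expect_equal(r$baseline, 10)
  expect_equal(r$rise_time, 50)
  # same answer under the global-minimum rule here
  rg <- detect_etco2_rise(v, fs, c(0, 60), smoothing = 0,
                          baseline_rule = "global")
  expect_equal(rg$rise_time, 50)
  # never exceeding twice the minimum -> no event
  r0 <- detect_etco2_rise(ifelse(t < 35, 15, 10), fs, c(0, 60), smoothing = 0)
  expect_false(r0$met)
  expect_true(is.na(r0$rise_time))
  # non-positive baseline is a unit/offset problem
  expect_error(detect_etco2_rise(v - 20, fs, c(0, 60), smoothing = 0), "<= 0")
})

test_that("running vs global baseline rules differ when an early bump doubles", {
  fs <- 10
  t <- seq(0, 100, by = 1 / fs)
  # early: 5 then bump to 12 (doubles the early min), later: deep dip to 3
  # then surge to 30
  v <- ifelse(t < 10, 5, ifelse(t < 20, 12, ifelse(t < 60, 3, 30)))
  rr <- detect_etco2_rise(v, fs, c(0, 100), smoothing = 0)
  expect_equal(rr$rise_time, 10)   # fires on the early bump
  expect_equal(rr$baseline, 5)
  rg <- detect_etco2_rise(v, fs, c(0, 100), smoothing = 0,
                          baseline_rule = "global")
  expect_equal(rg$baseline, 3)     # anchored at the global minimum
  expect_equal(rg$rise_time, 60)
})

test_that("generator etCO2 is recovered exactly (noiseless) and within 1 s (noisy)", {
  cfg0 <- quick_config(noise_sd = 0,
                       etco2 = list(baseline = 28, dip_value = 20,
                                    surge_time = 25, surge_value = 48.7,
                                    transition_width = 3))
  sim0 <- generate_recording(cfg0)
  cpr <- c(sim0$truth$cpr_start, sim0$truth$rosc_time)
  r0 <- detect_etco2_rise(get_channel(sim0$recording, "etco2"),
                          cfg0$sampling_rate, cpr, smoothing = 0)
  expect_identical(r0$rise_time, sim0$truth$etco2_rise_time)

  for (seed in 1:5) {
    cfg <- quick_config(noise_sd = 0.5, rng_seed = seed)
    sim <- generate_recording(cfg)
    r <- detect_etco2_rise(get_channel(sim$recording, "etco2"),
                           cfg$sampling_rate,
                           c(sim$truth$cpr_start, sim$truth$rosc_time),
                           smoothing = 1)
    expect_lt(abs(r$rise_time - sim$truth$etco2_rise_time), 1)
  }
})

test_that("CPP is diastole minus interval-minimum CVP, invariant elsewhere", {
  fs <- 100
  cvp <- rep(12, 1000)
  cvp[300] <- 10
  dia <- data.frame(time = seq(1, 9, by = 1), value = rep(40, 9))
  r <- compute_cpp(dia, cvp, fs, c(0, 9.99))
  expect_equal(unique(r$series$value), 30)
  expect_equal(r$min_cvp, 10)
  # perturbing CVP anywhere above its minimum leaves CPP unchanged
  cvp2 <- cvp + runif(1000, 0, 5)
  cvp2[300] <- 10
  r2 <- compute_cpp(dia, cvp2, fs, c(0, 9.99))
  expect_equal(r2$series$value, r$series$value)
  # ramp example: diastole 20 -> 40, min CVP 12 -> CPP 8 -> 28, mean 18
  dia3 <- data.frame(time = 1:9, value = seq(20, 40, length.out = 9))
  cvp3 <- rep(12, 1000)
  r3 <- compute_cpp(dia3, cvp3, fs, c(0, 9.99))
  expect_equal(range(r3$series$value), c(8, 28))
  expect_equal(r3$mean, 18)
  expect_error(compute_cpp(dia, cvp, fs, c(5, 5)), "empty")
})

test_that("cycle amplitudes: sinusoid gives 2A, constants give 0", {
  fs <- 1000; A <- 3
  t <- (0:19999) / fs
  x <- 10 + A * sin(2 * pi * (200 / 60) * t)
  amp <- compute_cycle_amplitudes(x, fs, 200, c(0, 20))
  expect_equal(amp$value, rep(2 * A, nrow(amp)), tolerance = 1e-9)
  expect_true(all(diff(amp$time) > 0))
  amp0 <- compute_cycle_amplitudes(rep(7, 1000), fs, 200, c(0, 1))
  expect_true(all(amp0$value == 0))
  expect_warning(compute_cycle_amplitudes(x, fs, 200, c(0, 0.1)), "shorter")
})

test_that("time-domain cycle amplitude agrees with spectral PIVA within 10%", {
  # At the default 200/min the compression tone falls between FFT bins and
  # the single-bin estimate loses ~15% to rectangular-window scalloping
  # (verified against the brute-force DFT oracle in test-spectral), so the
  # cross-method consistency check runs (a) at an exact-bin rate with the
  # default estimator and (b) at 200/min with the leakage-robust band
  # estimator.
  A <- 4
  base_site <- list(tail = list(baseline_pressure = 13, peak_amplitude = A,
                                peak_time = 20, rise_width = 1e6,
                                fall_width = 1e6))
  for (case in list(list(rate = 234.375, method = "bin"),    # 32 * fs / 8192 Hz
                    list(rate = 200, method = "band"))) {
    cfg <- quick_config(sites = base_site, ventilation_fraction = 0,
                        noise_sd = 0, compression_rate = case$rate)
    sim <- generate_recording(cfg)
    cpr <- c(sim$truth$cpr_start, sim$truth$rosc_time)
    amp <- compute_cycle_amplitudes(get_channel(sim$recording, "tail_venous"),
                                    cfg$sampling_rate, cfg$compression_rate,
                                    cpr)
    p <- extract_piva(sim$recording, "tail_venous", method = case$method)
    piva_cpr <- p$value[p$window_start >= cpr[1] &
                          p$window_start + 8.192 <= cpr[2]]
    expect_true(all(abs(mean(amp$value) / 2 - piva_cpr) / piva_cpr < 0.1))
  }
})

test_that("quarter summary: constants, ramp, and exact conservation", {
  rec <- tone_recording(duration = 20)
  rec$annotations$cpr_start <- 0
  rec$annotations$rosc_time <- 20
  const <- data.frame(time = seq(0.5, 19.5, by = 1), value = 7)
  ramp_t <- seq(0, 20, length.out = 4000)
  ramp <- data.frame(time = ramp_t, value = ramp_t / 20)
  qs <- summarize_quarters(rec, list(const = const, ramp = ramp))
  expect_s3_class(qs, "piva_quarter_summary")
  cr <- qs[qs$metric == "const", ]
  expect_equal(unlist(cr[c("q1", "q2", "q3", "q4")], use.names = FALSE),
               rep(7, 4))
  rr <- unlist(qs[qs$metric == "ramp", c("q1", "q2", "q3", "q4")],
               use.names = FALSE)
  expect_equal(rr, c(0.125, 0.375, 0.625, 0.875), tolerance = 0.01)
  # equal-count quarters: mean of quarter means = overall mean, exactly
  n_per_q <- unlist(qs[qs$metric == "const", c("n1", "n2", "n3", "n4")])
  expect_true(length(unique(n_per_q)) == 1)
  expect_equal(mean(unlist(cr[c("q1", "q2", "q3", "q4")])), mean(const$value),
               tolerance = 1e-9)
  # empty quarter -> NA with a message
  sparse <- data.frame(time = c(1, 2), value = c(1, 2))
  expect_message(qs2 <- summarize_quarters(rec, list(sparse = sparse)),
                 "no observations")
  expect_true(is.na(qs2$q4))
})

test_that("arterial per-cycle metrics: offset + sinusoid decomposes exactly", {
  fs <- 1000; O <- 50; A <- 10
  t <- (0:29999) / fs
  x <- O + A * sin(2 * pi * (200 / 60) * t)
  m <- derive_arterial_metrics(x, fs, 200, c(0, 30))
  expect_equal(m$systole$value, rep(O + A, nrow(m$systole)), tolerance = 1e-6)
  expect_equal(m$diastole$value, rep(O - A, nrow(m$diastole)), tolerance = 1e-6)
  expect_equal(m$map$value, rep(O, nrow(m$map)), tolerance = 1e-6)
  # first cycle reaching a systolic threshold is identifiable
  ramp <- x + seq(0, 80, length.out = length(x))
  ms <- derive_arterial_metrics(ramp, fs, 200, c(0, 30))
  i120 <- which(ms$systole$value >= 120)[1]
  expect_true(is.finite(i120))
  expect_true(all(ms$systole$value[seq_len(i120 - 1)] < 120))
})

test_that("detect_events assembles a consistent event set", {
  sim <- generate_recording(quick_config(rng_seed = 9))
  det <- detect_events(sim$recording)
  es <- det$event_set
  expect_s3_class(es, "piva_event_set")
  expect_equal(es$rosc_time, sim$recording$annotations$rosc_time)
  expect_setequal(names(es$piva_peak_time),
                  c("tail_venous", "femoral_venous", "central_venous"))
  cpr <- c(sim$truth$cpr_start, sim$truth$rosc_time)
  for (ch in names(es$piva_peak_time)) {
    expect_true(es$piva_peak_time[[ch]] >= cpr[1] &&
                  es$piva_peak_time[[ch]] <= cpr[2])
    expect_true(es$piva_peak_value[[ch]] > 0)
  }
  expect_true(es$etco2_rise_time > cpr[1] && es$etco2_rise_time < cpr[2])
  expect_true(es$etco2_baseline > 0)
})
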