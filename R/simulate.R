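#' Simulation configuration for a synthetic CPR recording
#'
#' Describes a single CPR epoch: a pre-compression baseline, a CPR interval
#' during which a mechanical compression train (nominal 200 per minute)
#' rides on each venous channel under a site-specific rise-peak-fall
#' amplitude envelope, an arterial pressure ramp, and an end-tidal CO2 trace
#' that dips early in CPR and surges (more than doubling) shortly before
#' ROSC. Defaults encode the published rat asphyxial-arrest scenario: 1 kHz
#' sampling, 55 s of CPR, compressions at 200/min, ventilation at 60/min,
#' venous envelope magnitudes of order tail ~1, femoral ~3, central ~5 mmHg
#' with peak times staggered tail < femoral < central, a mean arterial
#' pressure ramp 14.4 -> 81.7 mmHg, and an etCO2 surge to 48.7 mmHg.
#'
#' @param sampling_rate Hz (default 1000).
#' @param pre_cpr_duration,cpr_duration,post_rosc_duration seconds; CPR runs
#'   from `pre_cpr_duration` to `pre_cpr_duration + cpr_duration`, and ROSC
#'   is annotated at the moment compressions stop.
#' @param compression_rate,ventilation_rate per minute.
#' @param sites named list (names are venous channel sites, conventionally
#'   `tail`, `femoral`, `central`); each element a list with
#'   `baseline_pressure` (mmHg), `peak_amplitude` (mmHg, the sinusoid
#'   amplitude at the envelope maximum; peak-to-trough is twice this),
#'   `peak_time` (s from CPR start, in \[0, cpr_duration\]), `rise_width`,
#'   `fall_width` (s; Gaussian SDs of the asymmetric envelope, or ramp
#'   half-widths for the piecewise-linear family).
#' @param arterial list: `start_map`, `end_map` (mmHg, the linear
#'   mean-pressure ramp endpoints over CPR), `pulse_amplitude` (mmHg,
#'   compression-synchronous sinusoid amplitude; peak-to-trough is twice
#'   this).
#' @param etco2 list: `baseline` (mmHg, early plateau), `dip_value` (mmHg,
#'   low plateau during CPR), `surge_time` (s from CPR start), `surge_value`
#'   (mmHg; must exceed `2 * dip_value` so the doubling rule is reachable),
#'   `transition_width` (s, 10-90% logistic rise duration).
#' @param ventilation_fraction amplitude of the ventilation-frequency
#'   component on venous channels, as a fraction of the site's
#'   `peak_amplitude` (default 0.1; set 0 to disable).
#' @param noise_sd additive white Gaussian noise SD, mmHg (all channels).
#' @param pulse_shape compression pulse shape; see
#'   [generate_compression_train()].
#' @param envelope_family `"gaussian"` (asymmetric Gaussian, default) or
#'   `"linear"` (piecewise-linear rise/fall).
#' @param rng_seed integer seed; identical configs generate bit-identical
#'   recordings.
#' @return a validated list of class `piva_sim_config`.
#' @export
sim_config <- function(sampling_rate = 1000,
                       pre_cpr_duration = 10,
                       cpr_duration = 55,
                       post_rosc_duration = 15,
                       compression_rate = 200,
                       ventilation_rate = 60,
                       sites = list(
                         tail = list(baseline_pressure = 13, peak_amplitude = 1,
                                     peak_time = 20.3, rise_width = 15,
                                     fall_width = 12),
                         femoral = list(baseline_pressure = 14, peak_amplitude = 3,
                                        peak_time = 24.1, rise_width = 18,
                                        fall_width = 15),
                         central = list(baseline_pressure = 13.5, peak_amplitude = 5,
                                        peak_time = 29.9, rise_width = 20,
                                        fall_width = 30)
                       ),
                       arterial = list(start_map = 14.4, end_map = 81.7,
                                       pulse_amplitude = 10),
                       etco2 = list(baseline = 28, dip_value = 18,
                                    surge_time = 33.5, surge_value = 48.7,
                                    transition_width = 3),
                       ventilation_fraction = 0.1,
                       noise_sd = 0.1,
                       pulse_shape = c("sinusoid", "rectified_sinusoid",
                                       "gaussian_pulse"),
                       envelope_family = c("gaussian", "linear"),
                       rng_seed = 1L) {
  cfg <- list(
    sampling_rate = sampling_rate,
    pre_cpr_duration = pre_cpr_duration,
    cpr_duration = cpr_duration,
    post_rosc_duration = post_rosc_duration,
    compression_rate = compression_rate,
    ventilation_rate = ventilation_rate,
    sites = sites, arterial = arterial, etco2 = etco2,
    ventilation_fraction = ventilation_fraction,
    noise_sd = noise_sd,
    pulse_shape = match.arg(pulse_shape),
    envelope_family = match.arg(envelope_family),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "piva_sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  pos_scalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!pos_scalar(cfg$sampling_rate) || cfg$sampling_rate <= 0) {
    stop("sampling_rate must be positive")
  }
  for (f in c("pre_cpr_duration", "post_rosc_duration")) {
    if (!pos_scalar(cfg[[f]]) || cfg[[f]] < 0) stop(f, " must be >= 0")
  }
  if (!pos_scalar(cfg$cpr_duration) || cfg$cpr_duration <= 0) {
    stop("cpr_duration must be > 0")
  }
  if (!pos_scalar(cfg$compression_rate) || cfg$compression_rate <= 0) {
    stop("compression_rate must be positive")
  }
  if (!pos_scalar(cfg$ventilation_rate) || cfg$ventilation_rate <= 0) {
    stop("ventilation_rate must be positive")
  }
  if (!pos_scalar(cfg$noise_sd) || cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (!pos_scalar(cfg$ventilation_fraction) || cfg$ventilation_fraction < 0) {
    stop("ventilation_fraction must be >= 0")
  }
  for (site in names(cfg$sites)) {
    s <- cfg$sites[[site]]
    need <- c("baseline_pressure", "peak_amplitude", "peak_time",
              "rise_width", "fall_width")
    miss <- setdiff(need, names(s))
    if (length(miss)) {
      stop("site '", site, "' missing envelope params: ",
           paste(miss, collapse = ", "))
    }
    if (s$peak_time < 0 || s$peak_time > cfg$cpr_duration) {
      stop("site '", site, "': peak_time must lie in [0, cpr_duration]")
    }
    if (s$peak_amplitude < 0) stop("site '", site, "': peak_amplitude must be >= 0")
    if (s$rise_width <= 0 || s$fall_width <= 0) {
      stop("site '", site, "': rise_width and fall_width must be > 0")
    }
  }
  e <- cfg$etco2
  if (e$surge_value <= 2 * e$dip_value) {
    stop("etco2 surge_value (", e$surge_value, ") must exceed 2 * dip_value (",
         2 * e$dip_value, "): the >100% rise rule would never trigger")
  }
  if (e$surge_time < 0 || e$surge_time > cfg$cpr_duration) {
    stop("etco2 surge_time must lie within the CPR interval")
  }
  if (e$dip_value <= 0) stop("etco2 dip_value must be positive")
  cfg
}

#' Unit-amplitude chest-compression oscillation
#'
#' Periodic signal at the compression fundamental `rate / 60` Hz with
#' peak-to-trough span 2 (values in \[-1, 1\]).
#'
#' @param rate compressions per minute (> 0).
#' @param duration seconds (> 0).
#' @param sampling_rate Hz (> 0).
#' @param pulse_shape `"sinusoid"`, `"rectified_sinusoid"` (half-wave
#'   rectified, preserving the fundamental), or `"gaussian_pulse"` (one
#'   Gaussian bump per period, SD = period / 8).
#' @param phase_origin time offset in seconds applied to the oscillation
#'   argument (the train evaluates at `t + phase_origin`).
#' @return numeric vector of `round(duration * sampling_rate)` samples.
#' @export
generate_compression_train <- function(rate, duration, sampling_rate,
                                       pulse_shape = c("sinusoid",
                                                       "rectified_sinusoid",
                                                       "gaussian_pulse"),
                                       phase_origin = 0) {
  pulse_shape <- match.arg(pulse_shape)
  if (!is.numeric(rate) || rate <= 0) stop("rate must be positive (got ", rate, ")")
  if (!is.numeric(duration) || duration <= 0) {
    stop("duration must be positive (got ", duration, ")")
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be positive (got ", sampling_rate, ")")
  }
  n <- round(duration * sampling_rate)
  t <- (seq_len(n) - 1) / sampling_rate + phase_origin
  pulse_wave(t, rate / 60, pulse_shape)
}

# Unit-amplitude periodic pulse evaluated at times t (seconds), fundamental
# frequency f Hz, values spanning [-1, 1].
pulse_wave <- function(t, f, shape) {
  switch(shape,
    sinusoid = sin(2 * pi * f * t),
    rectified_sinusoid = 2 * pmax(sin(2 * pi * f * t), 0) - 1,
    gaussian_pulse = {
      period <- 1 / f
      sd <- period / 8
      tt <- t - period * floor(t / period)
      g <- exp(-(tt - period / 2)^2 / (2 * sd^2))
      gmin <- exp(-(period / 2)^2 / (2 * sd^2))
      2 * (g - gmin) / (1 - gmin) - 1
    },
    stop("unknown pulse shape: ", shape))
}

# Unimodal amplitude envelope on the CPR interval, maximum exactly at
# peak_time. t is time since CPR start; values outside [0, cpr_duration]
# are not this function's concern (callers gate on the CPR interval).
site_envelope <- function(t, site_params, family = "gaussian") {
  a <- site_params$peak_amplitude
  tp <- site_params$peak_time
  rw <- site_params$rise_width
  fw <- site_params$fall_width
  if (family == "gaussian") {
    ifelse(t <= tp,
           a * exp(-(t - tp)^2 / (2 * rw^2)),
           a * exp(-(t - tp)^2 / (2 * fw^2)))
  } else {
    ifelse(t <= tp,
           a * pmax(0, 1 - (tp - t) / rw),
           a * pmax(0, 1 - (t - tp) / fw))
  }
}

# Logistic 0 -> 1 with 10-90% rise time = width seconds, centered at t0.
smooth_step <- function(t, t0, width) {
  tau <- width / (2 * log(9))  # 10-90% duration = 2*log(9)*tau
  1 / (1 + exp(-(t - t0) / tau))
}

#' Synthetic venous pressure channel
#'
#' Baseline pressure plus a compression-frequency oscillation whose
#' amplitude follows the site's unimodal envelope over the CPR interval,
#' plus a small ventilation-frequency component (10% of the envelope peak,
#' from CPR start when ventilation resumes) and Gaussian noise. Outside the
#' CPR interval the compression component is zero.
#'
#' @param config a [sim_config()].
#' @param site name of an entry in `config$sites`.
#' @return list with `samples` (mmHg) and `true_peak_time` (s from
#'   recording start: `cpr_start + peak_time`).
#' @export
generate_venous_channel <- function(config, site) {
  if (!site %in% names(config$sites)) {
    stop("no envelope parameters for site '", site, "' (have: ",
         paste(names(config$sites), collapse = ", "), ")")
  }
  sp <- config$sites[[site]]
  fs <- config$sampling_rate
  total <- config$pre_cpr_duration + config$cpr_duration + config$post_rosc_duration
  n <- round(total * fs)
  t <- (seq_len(n) - 1) / fs
  cpr_start <- config$pre_cpr_duration
  tc <- t - cpr_start  # time since CPR start
  in_cpr <- tc >= 0 & tc < config$cpr_duration
  x <- rep(sp$baseline_pressure, n)
  if (any(in_cpr)) {
    f <- config$compression_rate / 60
    env <- site_envelope(tc[in_cpr], sp, config$envelope_family)
    x[in_cpr] <- x[in_cpr] + env * pulse_wave(tc[in_cpr], f, config$pulse_shape)
  }
  if (config$ventilation_fraction > 0) {
    vent <- tc >= 0
    fv <- config$ventilation_rate / 60
    x[vent] <- x[vent] +
      config$ventilation_fraction * sp$peak_amplitude * sin(2 * pi * fv * tc[vent])
  }
  if (config$noise_sd > 0) x <- x + stats::rnorm(n, 0, config$noise_sd)
  list(samples = x, true_peak_time = cpr_start + sp$peak_time)
}

#' Synthetic arterial pressure channel
#'
#' Mean pressure holds at `start_map` before CPR, ramps linearly to
#' `end_map` over the CPR interval, then holds. A compression-synchronous
#' sinusoid of amplitude `pulse_amplitude` is superimposed during CPR.
#'
#' @param config a [sim_config()].
#' @return numeric vector of samples (mmHg).
#' @export
generate_arterial_channel <- function(config) {
  ap <- config$arterial
  if (ap$end_map < ap$start_map) {
    warning("arterial ramp is decreasing (end_map < start_map)")
  }
  fs <- config$sampling_rate
  total <- config$pre_cpr_duration + config$cpr_duration + config$post_rosc_duration
  n <- round(total * fs)
  t <- (seq_len(n) - 1) / fs
  tc <- t - config$pre_cpr_duration
  frac <- pmin(pmax(tc / config$cpr_duration, 0), 1)
  x <- ap$start_map + (ap$end_map - ap$start_map) * frac
  in_cpr <- tc >= 0 & tc < config$cpr_duration
  f <- config$compression_rate / 60
  x[in_cpr] <- x[in_cpr] + ap$pulse_amplitude * sin(2 * pi * f * tc[in_cpr])
  if (config$noise_sd > 0) x <- x + stats::rnorm(n, 0, config$noise_sd)
  x
}

#' Synthetic end-tidal CO2 channel
#'
#' The noiseless trace sits at `baseline` into early CPR, descends
#' logistically to `dip_value` (centered 15% into the CPR interval), then
#' surges logistically to `surge_value` centered at `surge_time`. The ground
#' truth rise time is the first instant the noiseless trace exceeds twice
#' its running minimum over the CPR interval so far (the doubling rule the
#' detector applies).
#'
#' @param config a [sim_config()].
#' @return list with `samples` (mmHg) and `true_rise_time` (s from recording
#'   start).
#' @export
generate_etco2 <- function(config) {
  e <- config$etco2
  if (e$surge_value <= 2 * e$dip_value) {
    stop("etco2 surge_value must exceed 2 * dip_value")
  }
  fs <- config$sampling_rate
  total <- config$pre_cpr_duration + config$cpr_duration + config$post_rosc_duration
  n <- round(total * fs)
  t <- (seq_len(n) - 1) / fs
  cpr_start <- config$pre_cpr_duration
  dip_center <- cpr_start + 0.15 * config$cpr_duration
  rise_center <- cpr_start + e$surge_time
  v <- e$baseline +
    (e$dip_value - e$baseline) * smooth_step(t, dip_center, e$transition_width) +
    (e$surge_value - e$dip_value) * smooth_step(t, rise_center, e$transition_width)
  in_cpr <- which(t >= cpr_start & t <= cpr_start + config$cpr_duration)
  vc <- v[in_cpr]
  crossed <- vc > 2 * cummin(vc)
  if (!any(crossed)) {
    stop("internal: accepted etco2 config produced no detectable doubling")
  }
  true_rise_time <- t[in_cpr[which(crossed)[1]]]
  if (config$noise_sd > 0) v <- v + stats::rnorm(n, 0, config$noise_sd)
  list(samples = v, true_rise_time = true_rise_time)
}

#' Generate a complete synthetic CPR recording with ground truth
#'
#' Assembles channels `tail_venous`, `femoral_venous`, `central_venous`
#' (one per configured site, in config order, named `<site>_venous`),
#' `arterial`, and `etco2` into a [recording()], seeding the RNG once from
#' `config$rng_seed` so identical configs give bit-identical recordings.
#'
#' @param config a [sim_config()].
#' @return list with elements `recording` (a `piva_recording`) and `truth`
#'   (class `piva_ground_truth`: `cpr_start`, `rosc_time`, named
#'   `piva_peak_time` per venous channel, `etco2_rise_time`,
#'   `compression_frequency` in Hz).
#' @export
generate_recording <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$rng_seed)
  cpr_start <- config$pre_cpr_duration
  rosc_time <- cpr_start + config$cpr_duration
  cols <- list()
  kinds <- character(0)
  peak_times <- numeric(0)
  for (site in names(config$sites)) {
    ch <- paste0(site, "_venous")
    v <- generate_venous_channel(config, site)
    cols[[ch]] <- v$samples
    kinds[ch] <- "venous"
    peak_times[ch] <- v$true_peak_time
  }
  cols[["arterial"]] <- generate_arterial_channel(config)
  kinds["arterial"] <- "arterial"
  co2 <- generate_etco2(config)
  cols[["etco2"]] <- co2$samples
  kinds["etco2"] <- "etco2"
  rec <- recording(
    samples = do.call(cbind, cols),
    sampling_rate = config$sampling_rate,
    channel_kinds = kinds,
    annotations = list(cpr_start = cpr_start, rosc_time = rosc_time,
                       nominal_compression_rate = config$compression_rate)
  )
  truth <- structure(
    list(cpr_start = cpr_start,
         rosc_time = rosc_time,
         piva_peak_time = peak_times,
         etco2_rise_time = co2$true_rise_time,
         compression_frequency = config$compression_rate / 60),
    class = "piva_ground_truth"
  )
  stopifnot(all(truth$piva_peak_time >= cpr_start),
            all(truth$piva_peak_time <= rosc_time),
            truth$etco2_rise_time >= cpr_start,
            truth$etco2_rise_time <= rosc_time)
  list(recording = rec, truth = truth)
}
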