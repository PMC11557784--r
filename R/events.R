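#' Locate the PIVA amplitude peak
#'
#' The maximum PIVA value whose window center lies inside `interval`,
#' reported at the window-center time; ties go to the earliest window. A
#' monotonically increasing series therefore peaks at its last window (the
#' steadily rising central-venous pattern).
#'
#' @param piva a `piva_series` from [extract_piva()].
#' @param interval numeric length-2, seconds; default the CPR interval is
#'   supplied by the caller.
#' @param min_prominence optional minimum drop (mmHg) between the peak and
#'   the lower of the series values flanking it; 0 (default) disables the
#'   check (a plain argmax, which the single prominent peak of these data
#'   makes sufficient).
#' @return list with `time` (s), `value` (mmHg), `window_index`.
#' @export
detect_piva_peak <- function(piva, interval, min_prominence = 0) {
  stopifnot(length(interval) == 2L, interval[1] < interval[2])
  sel <- which(piva$time >= interval[1] & piva$time <= interval[2])
  if (!length(sel)) {
    stop("no PIVA windows with centers inside [", interval[1], ", ",
         interval[2], "] s; use a smaller hop or a longer recording")
  }
  v <- piva$value[sel]
  i <- sel[which.max(v)]  # first maximum = earliest on ties
  if (min_prominence > 0) {
    flank <- c(if (i > 1L) min(piva$value[seq_len(i - 1L)]) else Inf,
               if (i < nrow(piva)) min(piva$value[(i + 1L):nrow(piva)]) else Inf)
    if (piva$value[i] - max(flank[is.finite(flank)], -Inf) < min_prominence &&
        any(is.finite(flank))) {
      warning("PIVA peak prominence below ", min_prominence, " mmHg")
    }
  }
  list(time = piva$time[i], value = piva$value[i], window_index = i)
}

# Centered moving average with shrinking windows at the edges, so no NA
# padding biases the first/last seconds of the trace.
moving_average <- function(x, width_samples) {
  w <- max(1L, as.integer(round(width_samples)))
  if (w == 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- w %/% 2
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (w - half - 1L), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect the end-tidal CO2 doubling event
#'
#' Applies the published rule: a significant etCO2 increase is a rise of
#' more than 100% over the first lowest value during CPR. With the default
#' `baseline_rule = "running"` the trace is compared against its running
#' minimum, so the event fires the first instant the (optionally smoothed)
#' trace exceeds twice the lowest value seen so far in the interval, and the
#' baseline reported is that running minimum. The alternative `"global"`
#' rule fixes the baseline at the interval's global minimum first and then
#' looks for the first crossing after it.
#'
#' @param etco2 numeric vector of samples (mmHg).
#' @param sampling_rate Hz.
#' @param interval numeric length-2 in seconds (typically CPR start to
#'   ROSC).
#' @param smoothing moving-average width in seconds (default 1; 0 disables,
#'   leaving the raw samples).
#' @param baseline_rule `"running"` (default) or `"global"`.
#' @return list with `baseline` (mmHg), `rise_time` (s, or `NA_real_` when
#'   the rule is never met), `met` (logical).
#' @export
detect_etco2_rise <- function(etco2, sampling_rate, interval, smoothing = 1,
                              baseline_rule = c("running", "global")) {
  baseline_rule <- match.arg(baseline_rule)
  stopifnot(length(interval) == 2L, interval[1] < interval[2])
  n <- length(etco2)
  t <- (seq_len(n) - 1) / sampling_rate
  if (interval[1] < 0 || interval[2] > (n - 1) / sampling_rate + 1e-9) {
    stop("interval extends beyond the recording")
  }
  v <- if (smoothing > 0) {
    moving_average(etco2, smoothing * sampling_rate)
  } else {
    etco2
  }
  sel <- which(t >= interval[1] & t <= interval[2])
  vv <- v[sel]
  tt <- t[sel]
  if (min(vv) <= 0) {
    stop("etCO2 minimum in interval is <= 0 mmHg; the relative (>100%) rule ",
         "is undefined — check units/offsets")
  }
  if (baseline_rule == "running") {
    run_min <- cummin(vv)
    hit <- which(vv > 2 * run_min)
    if (!length(hit)) {
      return(list(baseline = min(vv), rise_time = NA_real_, met = FALSE))
    }
    i <- hit[1]
    list(baseline = run_min[i], rise_time = tt[i], met = TRUE)
  } else {
    b_idx <- which.min(vv)  # first occurrence of the global minimum
    baseline <- vv[b_idx]
    after <- which(seq_along(vv) > b_idx & vv > 2 * baseline)
    if (!length(after)) {
      return(list(baseline = baseline, rise_time = NA_real_, met = FALSE))
    }
    list(baseline = baseline, rise_time = tt[after[1]], met = TRUE)
  }
}

#' Coronary perfusion pressure
#'
#' CPP is diastolic arterial pressure minus the minimal central venous
#' pressure over the CPR interval. The CVP minimum is a single scalar for
#' the interval, so CPP inherits the diastolic series' time axis.
#'
#' @param diastolic data.frame with columns `time` (s) and `value` (mmHg),
#'   e.g. the `diastole` series from [derive_arterial_metrics()], or a bare
#'   numeric vector of per-cycle values.
#' @param cvp numeric vector of central venous pressure samples (mmHg).
#' @param sampling_rate Hz (for `cvp`).
#' @param interval numeric length-2, seconds.
#' @return list with `series` (data.frame `time`, `value`), `mean` (mmHg),
#'   `min_cvp` (mmHg).
#' @export
compute_cpp <- function(diastolic, cvp, sampling_rate, interval) {
  stopifnot(length(interval) == 2L)
  if (interval[1] >= interval[2]) stop("empty CPP interval")
  t <- (seq_along(cvp) - 1) / sampling_rate
  sel <- t >= interval[1] & t <= interval[2]
  if (!any(sel)) stop("no CVP samples inside interval")
  min_cvp <- min(cvp[sel])
  if (is.data.frame(diastolic)) {
    keep <- diastolic$time >= interval[1] & diastolic$time <= interval[2]
    ser <- data.frame(time = diastolic$time[keep],
                      value = diastolic$value[keep] - min_cvp)
  } else {
    ser <- data.frame(time = NA_real_, value = diastolic - min_cvp)
  }
  list(series = ser, mean = mean(ser$value), min_cvp = min_cvp)
}

# Clock-based segmentation of an interval into consecutive nominal
# compression periods; returns per-period index ranges and center times.
cycle_bounds <- function(n, sampling_rate, compression_rate, interval) {
  period <- sampling_rate * 60 / compression_rate  # samples, possibly fractional
  i0 <- floor(interval[1] * sampling_rate) + 1
  i1 <- min(floor(interval[2] * sampling_rate) + 1, n)
  n_cycles <- floor((i1 - i0 + 1) / period)
  if (n_cycles < 1) return(NULL)
  starts <- round(i0 + (seq_len(n_cycles) - 1) * period)
  ends <- round(i0 + seq_len(n_cycles) * period) - 1
  list(starts = starts, ends = pmin(ends, n),
       center = ((starts + ends) / 2 - 1) / sampling_rate)
}

#' Per-cycle peak-to-trough amplitudes
#'
#' Partitions the interval into consecutive nominal compression periods
#' (`sampling_rate * 60 / compression_rate` samples each; the trailing
#' partial period is dropped) and reports max - min per period. This is the
#' time-domain amplitude used in quarter summaries, distinct from the
#' FFT-derived PIVA value.
#'
#' @param samples numeric vector (mmHg).
#' @param sampling_rate Hz.
#' @param compression_rate per minute (> 0).
#' @param interval numeric length-2, seconds.
#' @return data.frame with `time` (s, period centers) and `value` (mmHg);
#'   zero rows with a warning if the interval is shorter than one period.
#' @export
compute_cycle_amplitudes <- function(samples, sampling_rate, compression_rate,
                                     interval) {
  if (compression_rate <= 0) stop("compression_rate must be positive")
  cb <- cycle_bounds(length(samples), sampling_rate, compression_rate, interval)
  if (is.null(cb)) {
    warning("interval shorter than one compression period; empty series")
    return(data.frame(time = numeric(0), value = numeric(0)))
  }
  value <- vapply(seq_along(cb$starts), function(i) {
    seg <- samples[cb$starts[i]:cb$ends[i]]
    max(seg) - min(seg)
  }, numeric(1))
  data.frame(time = cb$center, value = value)
}

#' Per-cycle arterial metrics
#'
#' Same clock-based cycle segmentation as [compute_cycle_amplitudes()];
#' per compression cycle: systole = max, diastole = min, MAP = time average.
#'
#' @inheritParams compute_cycle_amplitudes
#' @return list of data.frames `map`, `systole`, `diastole`, each with
#'   columns `time` (s) and `value` (mmHg).
#' @export
derive_arterial_metrics <- function(samples, sampling_rate, compression_rate,
                                    interval) {
  if (compression_rate <= 0) stop("compression_rate must be positive")
  cb <- cycle_bounds(length(samples), sampling_rate, compression_rate, interval)
  if (is.null(cb)) {
    warning("interval shorter than one compression period; empty series")
    empty <- data.frame(time = numeric(0), value = numeric(0))
    return(list(map = empty, systole = empty, diastole = empty))
  }
  stat <- function(f) {
    v <- vapply(seq_along(cb$starts),
                function(i) f(samples[cb$starts[i]:cb$ends[i]]), numeric(1))
    data.frame(time = cb$center, value = v)
  }
  list(map = stat(mean), systole = stat(max), diastole = stat(min))
}

#' Quarter-segmented summary of hemodynamic metrics
#'
#' Splits the CPR interval \[cpr_start, rosc_time\] into four equal-duration
#' quarters and averages each supplied metric within each quarter —
#' normalizing recordings of different CPR durations onto a common layout.
#' Metrics are data.frames with `time`/`value` columns (per-cycle or
#' per-window series) or bare channel names, which are averaged sample-wise.
#'
#' @param rec a [recording()].
#' @param series named list of data.frames (`time` in seconds, `value` in
#'   mmHg). Entries that are single strings are taken as channel names and
#'   averaged directly from the samples.
#' @return data.frame of class `piva_quarter_summary`: one row per metric,
#'   columns `metric`, `q1`..`q4` (means, `NA` where a quarter holds no
#'   observations, with a message), `n1`..`n4` (observation counts).
#' @export
summarize_quarters <- function(rec, series) {
  ann <- rec$annotations
  edges <- seq(ann$cpr_start, ann$rosc_time, length.out = 5)
  rows <- lapply(names(series), function(nm) {
    s <- series[[nm]]
    if (is.character(s) && length(s) == 1L) {
      x <- get_channel(rec, s)
      s <- data.frame(time = (seq_along(x) - 1) / rec$sampling_rate, value = x)
    }
    m <- numeric(4); cnt <- integer(4)
    for (q in 1:4) {
      inq <- s$time >= edges[q] & (if (q < 4) s$time < edges[q + 1]
                                   else s$time <= edges[5])
      cnt[q] <- sum(inq)
      m[q] <- if (cnt[q] > 0) mean(s$value[inq]) else NA_real_
      if (cnt[q] == 0) {
        message("quarter ", q, " holds no observations for metric '", nm, "'")
      }
    }
    data.frame(metric = nm, q1 = m[1], q2 = m[2], q3 = m[3], q4 = m[4],
               n1 = cnt[1], n2 = cnt[2], n3 = cnt[3], n4 = cnt[4])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("piva_quarter_summary", "data.frame")
  out
}

#' Run all event detectors on one recording
#'
#' Extracts PIVA per venous channel, locates each channel's PIVA peak
#' within the CPR interval, and applies the etCO2 doubling rule, returning
#' the event set downstream timing statistics consume. `rosc_time` is the
#' recording's annotation, passed through untouched.
#'
#' @param rec a [recording()].
#' @param window_length,hop,search_band,taper,method passed to
#'   [extract_piva()].
#' @param etco2_smoothing seconds, see [detect_etco2_rise()].
#' @param etco2_rule `"running"` or `"global"`, see [detect_etco2_rise()].
#' @return list with `event_set` (class `piva_event_set`: `rosc_time`,
#'   named `piva_peak_time` / `piva_peak_value` per venous channel,
#'   `etco2_baseline`, `etco2_rise_time` (NA when the rule is never met))
#'   and `piva` (named list of `piva_series`).
#' @export
detect_events <- function(rec, window_length = 8192L, hop = window_length,
                          search_band = NULL, taper = "rect", method = "bin",
                          etco2_smoothing = 1, etco2_rule = "running") {
  ann <- rec$annotations
  cpr <- c(ann$cpr_start, ann$rosc_time)
  venous <- names(rec$channel_kinds)[rec$channel_kinds == "venous"]
  venous <- intersect(colnames(rec$samples), venous)
  piva <- list()
  peak_time <- peak_value <- stats::setNames(numeric(0), character(0))
  for (ch in venous) {
    p <- extract_piva(rec, ch, window_length = window_length, hop = hop,
                      search_band = search_band, taper = taper, method = method)
    piva[[ch]] <- p
    pk <- detect_piva_peak(p, cpr)
    peak_time[ch] <- pk$time
    peak_value[ch] <- pk$value
  }
  etco2_ch <- names(rec$channel_kinds)[rec$channel_kinds == "etco2"]
  etco2_baseline <- NA_real_
  etco2_rise_time <- NA_real_
  if (length(etco2_ch)) {
    rise <- detect_etco2_rise(get_channel(rec, etco2_ch[1]),
                              rec$sampling_rate, cpr,
                              smoothing = etco2_smoothing,
                              baseline_rule = etco2_rule)
    etco2_baseline <- rise$baseline
    etco2_rise_time <- rise$rise_time
    if (!rise$met) message("no etCO2 criterion met (trace never exceeded ",
                           "twice its lowest value during CPR)")
  }
  es <- structure(
    list(rosc_time = ann$rosc_time,
         piva_peak_time = as.list(peak_time),
         piva_peak_value = as.list(peak_value),
         etco2_baseline = etco2_baseline,
         etco2_rise_time = etco2_rise_time),
    class = "piva_event_set"
  )
  list(event_set = es, piva = piva)
}
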