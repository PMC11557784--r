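#' Segment a signal into fixed-length analysis windows
#'
#' Window i (1-based) starts at sample `(i - 1) * hop + 1`; only complete
#' windows are returned and a trailing partial window is discarded. The
#' default `hop = window_length` reproduces non-overlapping analysis.
#'
#' @param samples numeric vector.
#' @param window_length window length in samples (>= 2).
#' @param hop hop between window starts in samples (1 <= hop <= window_length
#'   when overlap is allowed; default `window_length`, i.e. no overlap).
#' @return list with `starts` (1-based start sample of each window) and
#'   `windows` (a `window_length` x n_windows matrix; zero columns with a
#'   warning when the signal is shorter than one window).
#' @export
segment_windows <- function(samples, window_length = 8192L,
                            hop = window_length) {
  window_length <- as.integer(window_length)
  hop <- as.integer(hop)
  if (window_length < 2L) stop("window_length must be >= 2")
  if (hop < 1L || hop > window_length) {
    stop("hop must satisfy 1 <= hop <= window_length")
  }
  n <- length(samples)
  if (n < window_length) {
    warning("signal (", n, " samples) shorter than one window (",
            window_length, "); returning no windows")
    return(list(starts = integer(0),
                windows = matrix(numeric(0), nrow = window_length, ncol = 0)))
  }
  n_win <- (n - window_length) %/% hop + 1L
  starts <- (seq_len(n_win) - 1L) * hop + 1L
  idx <- outer(seq_len(window_length) - 1L, starts, `+`)
  list(starts = starts,
       windows = matrix(samples[idx], nrow = window_length, ncol = n_win))
}

#' Single-sided amplitude spectrum of one analysis window
#'
#' The window mean is subtracted (the analysis concerns oscillation
#' amplitudes, not baseline pressure), an optional taper applied, and the
#' FFT scaled to single-sided amplitude: `2 |X_k| / N` for interior bins,
#' `|X_k| / N` at DC and Nyquist, so a pure sinusoid of amplitude A at an
#' exact bin frequency reads A at that bin. With `taper = "hann"` amplitudes
#' are compensated by the coherent gain (0.5), preserving that calibration.
#'
#' @param window_samples numeric vector (one window).
#' @param sampling_rate Hz.
#' @param taper `"rect"` (default, no apodization) or `"hann"`.
#' @param window_start start time of the window in seconds (metadata only,
#'   used in error messages and downstream timestamps).
#' @return object of class `piva_spectrum`: `frequency` (Hz, 0..Nyquist),
#'   `amplitude` (mmHg), `sampling_rate`, `window_length`, `window_start`.
#' @export
compute_amplitude_spectrum <- function(window_samples, sampling_rate,
                                       taper = c("rect", "hann"),
                                       window_start = 0) {
  taper <- match.arg(taper)
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be positive")
  }
  if (!all(is.finite(window_samples))) {
    stop("non-finite samples in window starting at t = ", window_start, " s")
  }
  n <- length(window_samples)
  x <- window_samples - mean(window_samples)
  gain <- 1
  if (taper == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)
    x <- x * w
    gain <- 0.5  # coherent gain of the Hann taper
  }
  X <- stats::fft(x)
  half <- n %/% 2
  amp <- Mod(X[seq_len(half + 1)]) / n
  amp[2:half] <- 2 * amp[2:half]  # interior bins carry both images
  amp <- amp / gain
  structure(
    list(frequency = (0:half) * sampling_rate / n,
         amplitude = amp,
         sampling_rate = sampling_rate,
         window_length = n,
         window_start = window_start),
    class = "piva_spectrum"
  )
}

#' Dominant frequency within a search band
#'
#' Returns the frequency of the maximum-amplitude bin inside `search_band`,
#' ties broken toward the lower frequency. The band restriction is absolute:
#' spectral peaks outside the band (e.g. the ventilation peak) can never be
#' selected. The DC bin is always excluded.
#'
#' @param spectrum a `piva_spectrum`.
#' @param search_band numeric length-2 interval in Hz, within (0, Nyquist\].
#' @return dominant frequency in Hz (a bin-center value).
#' @export
find_dominant_frequency <- function(spectrum, search_band) {
  stopifnot(inherits(spectrum, "piva_spectrum"), length(search_band) == 2L)
  nyq <- spectrum$sampling_rate / 2
  lo <- max(search_band[1], 0)
  hi <- min(search_band[2], nyq)
  sel <- which(spectrum$frequency >= lo & spectrum$frequency <= hi &
                 spectrum$frequency > 0)
  if (!length(sel)) {
    stop("search band [", search_band[1], ", ", search_band[2],
         "] Hz contains no frequency bins (bin spacing ",
         signif(spectrum$sampling_rate / spectrum$window_length, 6), " Hz)")
  }
  a <- spectrum$amplitude[sel]
  spectrum$frequency[sel[which.max(a)]]  # which.max: first (lowest-f) maximum
}

#' Default dominant-frequency search band
#'
#' Nominal compression frequency plus/minus `half_width` Hz, clipped to
#' (0, Nyquist).
#'
#' @param nominal_rate compressions per minute.
#' @param half_width Hz (default 1).
#' @param sampling_rate Hz, for Nyquist clipping (optional).
#' @return numeric length-2 band in Hz.
#' @export
compression_band <- function(nominal_rate, half_width = 1,
                             sampling_rate = NULL) {
  f <- nominal_rate / 60
  band <- c(max(f - half_width, .Machine$double.eps), f + half_width)
  if (!is.null(sampling_rate)) band[2] <- min(band[2], sampling_rate / 2)
  band
}

#' Per-window PIVA amplitude series
#'
#' For each complete analysis window of the chosen venous channel, computes
#' the single-sided amplitude spectrum and reports the amplitude at the
#' dominant frequency inside the compression search band — the PIVA value
#' for that window. Timestamps are window centers. Windows that do not
#' overlap the annotated CPR interval are retained but flagged
#' (`in_cpr = FALSE`).
#'
#' @param rec a [recording()].
#' @param channel channel name; non-venous channels are analyzed with a
#'   warning.
#' @param window_length samples per window (default 8192; 8.192 s at 1 kHz).
#' @param hop samples between window starts (default `window_length`, no
#'   overlap).
#' @param search_band Hz interval for the dominant-frequency search; default
#'   nominal compression frequency +/- 1 Hz.
#' @param taper `"rect"` or `"hann"`, see [compute_amplitude_spectrum()].
#' @param method `"bin"` (amplitude of the single dominant bin, default) or
#'   `"band"` (root-sum-square over the dominant bin +/- 1, more robust to
#'   spectral leakage).
#' @return data.frame of class `piva_series` with columns `time` (s, window
#'   center), `value` (mmHg), `frequency` (Hz, dominant bin), `window_start`
#'   (s), `in_cpr` (logical); attributes `channel`, `window_length`, `hop`.
#' @export
extract_piva <- function(rec, channel, window_length = 8192L,
                         hop = window_length, search_band = NULL,
                         taper = c("rect", "hann"),
                         method = c("bin", "band")) {
  taper <- match.arg(taper)
  method <- match.arg(method)
  x <- get_channel(rec, channel)
  if (rec$channel_kinds[[channel]] != "venous") {
    warning("channel '", channel, "' is not venous; PIVA is defined for ",
            "venous waveforms")
  }
  if (is.null(search_band)) {
    search_band <- compression_band(rec$annotations$nominal_compression_rate,
                                    sampling_rate = rec$sampling_rate)
  }
  fs <- rec$sampling_rate
  seg <- segment_windows(x, window_length, hop)
  n_win <- length(seg$starts)
  out <- data.frame(time = numeric(n_win), value = numeric(n_win),
                    frequency = numeric(n_win), window_start = numeric(n_win),
                    in_cpr = logical(n_win))
  cpr <- c(rec$annotations$cpr_start, rec$annotations$rosc_time)
  for (i in seq_len(n_win)) {
    t0 <- (seg$starts[i] - 1) / fs
    spec <- compute_amplitude_spectrum(seg$windows[, i], fs, taper = taper,
                                       window_start = t0)
    f_dom <- find_dominant_frequency(spec, search_band)
    k <- which(spec$frequency == f_dom)
    val <- if (method == "bin") {
      spec$amplitude[k]
    } else {
      ks <- intersect((k - 1L):(k + 1L), 2:length(spec$amplitude))
      sqrt(sum(spec$amplitude[ks]^2))
    }
    t1 <- t0 + window_length / fs
    out$time[i] <- t0 + window_length / (2 * fs)
    out$value[i] <- val
    out$frequency[i] <- f_dom
    out$window_start[i] <- t0
    out$in_cpr[i] <- t1 > cpr[1] && t0 < cpr[2]
  }
  structure(out, class = c("piva_series", "data.frame"), channel = channel,
            window_length = window_length, hop = hop)
}

#' Seconds of signal consumed by one analysis window
#'
#' Bookkeeping helper: at 1 kHz an 8192-sample window spans 8.192 s,
#' i.e. 8 whole seconds of continuous signal are required.
#'
#' @param window_length samples.
#' @param sampling_rate Hz.
#' @return list with `seconds` (exact, `window_length / sampling_rate`) and
#'   `whole_seconds` (`floor(seconds)`).
#' @export
window_duration <- function(window_length = 8192L, sampling_rate = 1000) {
  s <- window_length / sampling_rate
  list(seconds = s, whole_seconds = floor(s))
}
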