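#' Multi-channel CPR recording
#'
#' A `piva_recording` bundles uniformly sampled pressure / capnography
#' channels with the annotations the analysis pipeline needs: the time
#' compressions started (`cpr_start`), the time of return of spontaneous
#' circulation (`rosc_time`, an annotation, never detected), and the nominal
#' mechanical compression rate. All times are seconds from the first sample
#' (t = 0); all pressures are mmHg.
#'
#' @param samples numeric matrix, time points in rows, one column per channel.
#' @param sampling_rate sampling frequency in Hz (> 0).
#' @param channel_kinds named character vector mapping every channel name to
#'   one of `"venous"`, `"arterial"`, `"etco2"`, `"other"`.
#' @param annotations list with numeric scalars `cpr_start`, `rosc_time`
#'   (seconds) and `nominal_compression_rate` (per minute).
#'
#' @return an object of class `piva_recording` with elements `samples`,
#'   `sampling_rate`, `channel_kinds`, `annotations`.
#' @export
recording <- function(samples, sampling_rate, channel_kinds, annotations) {
  samples <- as.matrix(samples)
  if (is.null(colnames(samples)) || anyDuplicated(colnames(samples))) {
    stop("samples must have unique channel names as column names")
  }
  storage.mode(samples) <- "double"
  rec <- structure(
    list(
      samples = samples,
      sampling_rate = as.numeric(sampling_rate),
      channel_kinds = channel_kinds,
      annotations = annotations
    ),
    class = "piva_recording"
  )
  validate_recording(rec)
}

validate_recording <- function(rec) {
  stopifnot(inherits(rec, "piva_recording"))
  if (!is.numeric(rec$sampling_rate) || length(rec$sampling_rate) != 1L ||
      !is.finite(rec$sampling_rate) || rec$sampling_rate <= 0) {
    stop("sampling_rate must be a single positive number")
  }
  if (nrow(rec$samples) < 1L) stop("recording must contain at least one sample")
  nm <- colnames(rec$samples)
  kinds <- rec$channel_kinds
  if (!all(nm %in% names(kinds))) {
    stop("channel_kinds missing entries for: ",
         paste(setdiff(nm, names(kinds)), collapse = ", "))
  }
  bad <- !kinds[nm] %in% c("venous", "arterial", "etco2", "other")
  if (any(bad)) {
    stop("unknown channel kind for: ", paste(nm[bad], collapse = ", "))
  }
  ann <- rec$annotations
  need <- c("cpr_start", "rosc_time", "nominal_compression_rate")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotations missing: ", paste(miss, collapse = ", "))
  for (f in need) {
    if (!is.numeric(ann[[f]]) || length(ann[[f]]) != 1L || !is.finite(ann[[f]])) {
      stop("annotation '", f, "' must be a finite numeric scalar")
    }
  }
  dur <- nrow(rec$samples) / rec$sampling_rate
  if (ann$cpr_start < 0 || ann$cpr_start >= ann$rosc_time) {
    stop("annotations must satisfy 0 <= cpr_start < rosc_time (got cpr_start = ",
         ann$cpr_start, ", rosc_time = ", ann$rosc_time, ")")
  }
  if (ann$rosc_time > dur + 1e-9) {
    stop("rosc_time (", ann$rosc_time, " s) exceeds recording duration (",
         signif(dur, 6), " s)")
  }
  if (ann$nominal_compression_rate <= 0) {
    stop("nominal_compression_rate must be positive")
  }
  rec
}

#' @export
print.piva_recording <- function(x, ...) {
  dur <- nrow(x$samples) / x$sampling_rate
  cat("piva_recording:", ncol(x$samples), "channels x", nrow(x$samples),
      "samples @", x$sampling_rate, "Hz (", signif(dur, 5), "s )\n")
  cat("  channels:", paste(sprintf("%s[%s]", colnames(x$samples),
                                   x$channel_kinds[colnames(x$samples)]),
                           collapse = ", "), "\n")
  a <- x$annotations
  cat(sprintf("  CPR %.3f -> ROSC %.3f s, nominal rate %g/min\n",
              a$cpr_start, a$rosc_time, a$nominal_compression_rate))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec a `piva_recording`.
#' @return duration `nrow(samples) / sampling_rate` in seconds.
#' @export
recording_duration <- function(rec) {
  nrow(rec$samples) / rec$sampling_rate
}

#' Time axis of a recording
#' @param rec a `piva_recording`.
#' @return numeric vector of sample times, seconds from the first sample.
#' @export
recording_times <- function(rec) {
  (seq_len(nrow(rec$samples)) - 1L) / rec$sampling_rate
}

#' Extract one channel as a numeric vector
#' @param rec a `piva_recording`.
#' @param channel channel name.
#' @return numeric vector of samples (mmHg).
#' @export
get_channel <- function(rec, channel) {
  if (!channel %in% colnames(rec$samples)) {
    stop("channel '", channel, "' not in recording (have: ",
         paste(colnames(rec$samples), collapse = ", "), ")")
  }
  rec$samples[, channel]
}
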