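#' Read a recording from CSV + JSON sidecar
#'
#' The canonical interchange format is a plain CSV of samples (header row of
#' channel names, optional leading `time` column) plus a JSON sidecar:
#'
#' ```json
#' {"sampling_rate_hz": 1000,
#'  "channels": [{"name": "tail_venous", "kind": "venous"}, ...],
#'  "annotations": {"cpr_start_s": 10, "rosc_time_s": 65,
#'                  "compression_rate_per_min": 200}}
#' ```
#'
#' All timestamps are seconds from the first sample. A `dialect = "chart"`
#' mode reads tab-delimited chart-recorder text exports instead: lines
#' beginning with `#` are skipped as header/comment lines and decimal commas
#' are accepted.
#'
#' @param csv_path path to the sample table.
#' @param sidecar_path path to the JSON sidecar.
#' @param dialect `"csv"` (default, RFC-4180 style) or `"chart"`
#'   (tab-delimited chart-recorder export).
#' @return a [recording()].
#' @export
read_recording <- function(csv_path, sidecar_path, dialect = c("csv", "chart")) {
  dialect <- match.arg(dialect)
  if (!file.exists(csv_path)) stop("sample file not found: ", csv_path)
  if (!file.exists(sidecar_path)) stop("sidecar not found: ", sidecar_path)
  side <- jsonlite::fromJSON(sidecar_path, simplifyVector = TRUE)
  if (is.null(side$sampling_rate_hz)) stop("sidecar missing sampling_rate_hz")
  if (is.null(side$annotations)) stop("sidecar missing annotations")
  ann_in <- side$annotations
  for (f in c("cpr_start_s", "rosc_time_s", "compression_rate_per_min")) {
    if (is.null(ann_in[[f]])) stop("sidecar annotations missing ", f)
  }
  if (dialect == "csv") {
    df <- utils::read.csv(csv_path, check.names = FALSE)
  } else {
    lines <- readLines(csv_path)
    lines <- lines[!startsWith(trimws(lines), "#")]
    lines <- gsub(",", ".", lines, fixed = TRUE)  # locale-safe decimals
    df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                            check.names = FALSE)
  }
  fs <- as.numeric(side$sampling_rate_hz)
  if ("time" %in% names(df)) {
    tm <- df[["time"]]
    implied <- (seq_len(nrow(df)) - 1) / fs
    if (any(abs(tm - implied) > 0.5 / fs)) {
      stop("time column conflicts with uniform sampling at ", fs, " Hz")
    }
    df <- df[, setdiff(names(df), "time"), drop = FALSE]
  }
  ch <- side$channels
  if (is.null(ch)) {
    kinds <- stats::setNames(rep("other", ncol(df)), names(df))
  } else {
    kinds <- stats::setNames(as.character(ch$kind), as.character(ch$name))
  }
  n_na <- vapply(df, function(x) sum(!is.na(x)), integer(1))
  if (length(unique(n_na)) > 1L) {
    stop("channels differ in length: ",
         paste(sprintf("%s=%d", names(n_na), n_na), collapse = ", "))
  }
  recording(
    samples = as.matrix(df),
    sampling_rate = fs,
    channel_kinds = kinds,
    annotations = list(
      cpr_start = as.numeric(ann_in$cpr_start_s),
      rosc_time = as.numeric(ann_in$rosc_time_s),
      nominal_compression_rate = as.numeric(ann_in$compression_rate_per_min)
    )
  )
}

#' Write a recording to CSV + JSON sidecar
#'
#' Inverse of [read_recording()]; the round trip preserves samples to the
#' chosen text precision and annotations exactly.
#'
#' @param rec a [recording()].
#' @param csv_path,sidecar_path output paths (directories are created).
#' @param digits significant digits for sample serialization (default 9).
#' @export
write_recording <- function(rec, csv_path, sidecar_path, digits = 9) {
  validate_recording(rec)
  if (nrow(rec$samples) == 0L) stop("refusing to write empty recording")
  for (p in c(csv_path, sidecar_path)) {
    d <- dirname(p)
    if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  }
  df <- as.data.frame(signif(rec$samples, digits))
  utils::write.csv(df, csv_path, row.names = FALSE)
  nm <- colnames(rec$samples)
  side <- list(
    sampling_rate_hz = rec$sampling_rate,
    channels = data.frame(name = nm, kind = unname(rec$channel_kinds[nm])),
    annotations = list(
      cpr_start_s = rec$annotations$cpr_start,
      rosc_time_s = rec$annotations$rosc_time,
      compression_rate_per_min = rec$annotations$nominal_compression_rate
    )
  )
  jsonlite::write_json(side, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Write analysis results for one recording
#'
#' Emits machine-readable outputs under `out_dir`: `events.json` (the event
#' set plus a provenance block), one `piva_<channel>.csv` per PIVA series,
#' `quarters.csv` (metrics in rows, the four CPR quarters in columns), and,
#' when given, `timing_table.csv` / `comparisons.json` from the stats stage.
#'
#' @param out_dir output directory (created if needed).
#' @param event_set a `piva_event_set` from [detect_events()], or NULL.
#' @param piva_collection named list of `piva_series` objects, or NULL.
#' @param quarter_summary data.frame from [summarize_quarters()], or NULL.
#' @param timing_result list from the stats stage (`timing_table`,
#'   `comparisons`), or NULL.
#' @param provenance named list recorded verbatim inside `events.json`.
#' @return invisibly, the paths written.
#' @export
write_results <- function(out_dir, event_set = NULL, piva_collection = NULL,
                          quarter_summary = NULL, timing_result = NULL,
                          provenance = list()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  if (!is.null(event_set)) {
    p <- file.path(out_dir, "events.json")
    payload <- unclass(event_set)
    payload$provenance <- c(list(package_version =
                                   as.character(utils::packageVersion("piva"))),
                            provenance)
    jsonlite::write_json(payload, p, auto_unbox = TRUE, digits = NA,
                         null = "null")
    written <- c(written, p)
  }
  for (ch in names(piva_collection)) {
    p <- file.path(out_dir, paste0("piva_", ch, ".csv"))
    utils::write.csv(as.data.frame(piva_collection[[ch]]), p, row.names = FALSE)
    written <- c(written, p)
  }
  if (!is.null(quarter_summary)) {
    p <- file.path(out_dir, "quarters.csv")
    utils::write.csv(quarter_summary, p, row.names = FALSE)
    written <- c(written, p)
  }
  if (!is.null(timing_result)) {
    if (!is.null(timing_result$timing_table)) {
      p <- file.path(out_dir, "timing_table.csv")
      utils::write.csv(timing_result$timing_table, p, row.names = FALSE)
      written <- c(written, p)
    }
    if (!is.null(timing_result$comparisons)) {
      p <- file.path(out_dir, "comparisons.json")
      jsonlite::write_json(timing_result$comparisons, p, auto_unbox = TRUE,
                           digits = NA, null = "null")
      written <- c(written, p)
    }
  }
  invisible(written)
}

#' Read an events.json written by [write_results()]
#' @param path path to `events.json`.
#' @return list with the event-set fields (times in seconds).
#' @export
read_events <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
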