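RECORDING_HEADER <- "time_s,motion_mm,trigger_V,beam_V"

#' Write a recording to delimited text
#'
#' One row per sample, header `time_s,motion_mm,trigger_V,beam_V`, preceded
#' by `#key=value` metadata comment lines. Times are serialized with six
#' decimals (a 0.1 ms grid at 10 kHz is exactly representable).
#'
#' @param recording A `gating_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  meta <- recording$metadata
  meta$sampling_rate_hz <- recording$sampling_rate
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", names(meta), "=",
                    vapply(meta, function(v) paste(format(v), collapse = ";"),
                           "")), con)
  writeLines(RECORDING_HEADER, con)
  writeLines(sprintf("%.6f,%.6g,%.6g,%.6g", recording$time,
                     recording$motion, recording$trigger, recording$beam),
             con)
  invisible(path)
}

#' Read a recording from delimited text
#'
#' Parses the CSV form written by [write_recording()]: leading `#key=value`
#' metadata comments, then the exact header
#' `time_s,motion_mm,trigger_V,beam_V`. The time axis must be uniform (the
#' sampling rate is inferred from it); deviations above 1 microsecond, NaN
#' samples or a malformed header are parse errors reporting the offending
#' line.
#'
#' @param path Path to the recording file.
#' @return A `gating_recording`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path))
    gatelat_abort(paste("file not found:", path), "io")
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  first_data <- which(!is_meta)[1]
  if (is.na(first_data))
    gatelat_abort("file contains no header line", "parse")
  header <- lines[first_data]
  if (header != RECORDING_HEADER) {
    want <- strsplit(RECORDING_HEADER, ",")[[1]]
    got <- strsplit(header, ",")[[1]]
    missing <- setdiff(want, got)
    msg <- if (length(missing))
      sprintf("line %d: header missing column(s): %s", first_data,
              paste(missing, collapse = ", "))
    else
      sprintf("line %d: malformed header '%s'", first_data, header)
    gatelat_abort(msg, "parse")
  }

  metadata <- list()
  for (ln in lines[seq_len(first_data - 1L)]) {
    kv <- sub("^#", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0)
      metadata[[substr(kv, 1, eq - 1)]] <-
        utils::type.convert(substr(kv, eq + 1, nchar(kv)), as.is = TRUE)
  }

  df <- utils::read.csv(text = lines[(first_data):length(lines)])
  if (!nrow(df))
    gatelat_abort("recording contains no samples", "parse")
  for (col in names(df)) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad))
      gatelat_abort(sprintf("line %d: non-finite value in column '%s'",
                            first_data + bad[1], col), "parse")
  }
  dt <- diff(df$time_s)
  if (any(dt <= 0) || max(dt) - min(dt) > 1e-6) {
    bad <- which(dt <= 0 | abs(dt - stats::median(dt)) > 1e-6)[1]
    gatelat_abort(sprintf("line %d: non-uniform time axis",
                          first_data + bad + 1L), "parse")
  }
  fs <- 1 / stats::median(dt)
  metadata$sampling_rate_hz <- NULL

  new_recording(time = df$time_s, motion = df$motion_mm,
                trigger = df$trigger_V, beam = df$beam_V,
                sampling_rate = fs, metadata = metadata)
}

#' Write simulator ground truth as JSON
#'
#' List of per-cycle objects; times in seconds, latencies in ms.
#'
#' @param truth Ground-truth data frame from [simulate_session()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read simulator ground truth from JSON
#'
#' @param path Path written by [write_ground_truth()].
#' @return Ground-truth data frame.
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path))
    gatelat_abort(paste("file not found:", path), "io")
  jsonlite::fromJSON(path)
}

#' Write per-cycle latencies as CSV
#'
#' Columns `cycle,tau_rpm_on_ms,tau_rpm_off_ms,tau_cyc_on_ms,tau_cyc_off_ms,
#' tau_total_on_ms,tau_total_off_ms,complete`; optional `#key=value`
#' provenance comment lines above the header.
#'
#' @param latencies Data frame from [compute_latencies()].
#' @param path Output file path.
#' @param provenance Optional named list for the comment header.
#' @param amplitude,period Optional scenario labels stored in the header.
#' @return `path`, invisibly.
#' @export
write_latencies <- function(latencies, path, provenance = NULL,
                            amplitude = NULL, period = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(list(amplitude_mm = amplitude, period_s = period), provenance)
  meta <- meta[!vapply(meta, is.null, TRUE)]
  if (length(meta))
    writeLines(paste0("#", names(meta), "=",
                      vapply(meta, function(v)
                        paste(format(v), collapse = ";"), "")), con)
  out <- latencies
  names(out) <- sub("^(tau_.*)$", "\\1_ms", names(out))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-cycle latencies from CSV
#'
#' @param path Path written by [write_latencies()].
#' @return List with `latencies` (data frame, `tau_*` column names without
#'   the `_ms` suffix) and `metadata` (parsed comment header).
#' @export
read_latencies <- function(path) {
  if (!file.exists(path))
    gatelat_abort(paste("file not found:", path), "io")
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  metadata <- list()
  for (ln in lines[is_meta]) {
    kv <- sub("^#", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0)
      metadata[[substr(kv, 1, eq - 1)]] <-
        utils::type.convert(substr(kv, eq + 1, nchar(kv)), as.is = TRUE)
  }
  df <- utils::read.csv(text = lines[!is_meta])
  names(df) <- sub("_ms$", "", names(df))
  list(latencies = df, metadata = metadata)
}
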