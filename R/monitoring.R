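# Streaming per-second monitoring: record ingestion, input extraction,
# pre-diagnosis timelines and debounced alert generation.

parse_timestamp <- function(ts) {
  if (inherits(ts, "POSIXct")) return(as.POSIXct(ts, tz = "UTC"))
  out <- as.POSIXct(ts, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                   "%Y-%m-%d %H:%M:%S"),
                    optional = TRUE)
  out
}

format_timestamp <- function(ts) format(ts, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

#' Read vital-sign records from CSV
#'
#' Two dialects are supported. `"wide"`: one row per second with columns
#' `patient_id`, `timestamp` and one column per channel (e.g. `ABP_mean`,
#' `ABP_sys`, `ABP_dia`, `SpO2`, plus any passthrough channels). `"long"`:
#' columns `patient_id`, `timestamp`, `channel`, `value`, reshaped to wide.
#' Rows with unparseable timestamps or non-numeric channel values are
#' dropped with a warning carrying the skip count; if more than half the
#' rows are malformed the read aborts. Records are returned ordered by
#' patient then time.
#'
#' @param path CSV file path.
#' @param dialect `"wide"` (default) or `"long"`.
#' @return Data.frame of records: `patient_id`, `timestamp` (POSIXct, UTC)
#'   and one numeric column per channel.
#' @export
read_records <- function(path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) {
    return(data.frame(patient_id = character(0),
                      timestamp = as.POSIXct(character(0), tz = "UTC")))
  }
  need <- if (dialect == "long") c("patient_id", "timestamp", "channel",
                                   "value")
          else c("patient_id", "timestamp")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("CSV missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  n_in <- nrow(raw)
  ts <- parse_timestamp(raw$timestamp)
  bad <- is.na(ts) | is.na(raw$patient_id) | raw$patient_id == ""
  if (dialect == "long") {
    val <- suppressWarnings(as.numeric(raw$value))
    bad <- bad | is.na(raw$channel) | raw$channel == "" |
      (is.na(val) & !is.na(raw$value) & raw$value != "")
    raw$value <- val
  } else {
    chan_cols <- setdiff(names(raw), c("patient_id", "timestamp"))
    for (cc in chan_cols) {
      v <- suppressWarnings(as.numeric(raw[[cc]]))
      bad <- bad | (is.na(v) & !is.na(raw[[cc]]) & raw[[cc]] != "")
      raw[[cc]] <- v
    }
  }
  n_bad <- sum(bad)
  if (n_bad > 0) {
    if (n_bad > n_in / 2)
      stop("more than 50% malformed rows (", n_bad, "/", n_in,
           "); aborting", call. = FALSE)
    warning(n_bad, " malformed row(s) skipped", call. = FALSE)
  }
  raw <- raw[!bad, , drop = FALSE]
  raw$timestamp <- ts[!bad]
  if (dialect == "long") {
    wide <- stats::reshape(
      raw[, c("patient_id", "timestamp", "channel", "value")],
      idvar = c("patient_id", "timestamp"), timevar = "channel",
      direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    raw <- wide
  }
  raw <- raw[order(raw$patient_id, raw$timestamp), , drop = FALSE]
  rownames(raw) <- NULL
  raw
}

#' Extract fuzzy-engine inputs from one record
#'
#' Mean blood pressure is taken from the `ABP_mean` channel when present;
#' otherwise it is reconstructed from systolic and diastolic pressure with
#' the standard estimate MAP = (SBP + 2 DBP) / 3 (flagged in
#' `mbp_source = "sys_dia"`). SpO2 is taken directly. Missing sources give
#' `NA` values rather than errors.
#'
#' @param record Named list or one-row data.frame of channel values.
#' @return List with `mbp`, `spo2` (numeric or `NA`) and `mbp_source`
#'   (`"ABP_mean"`, `"sys_dia"` or `NA`).
#' @export
extract_inputs <- function(record) {
  if (is.data.frame(record)) record <- as.list(record[1L, , drop = FALSE])
  g <- function(nm) {
    v <- record[[nm]]
    if (is.null(v) || length(v) == 0L || is.na(v)) NA_real_ else as.numeric(v)
  }
  mbp <- g("ABP_mean"); src <- "ABP_mean"
  if (is.na(mbp)) {
    sbp <- g("ABP_sys"); dbp <- g("ABP_dia")
    if (!is.na(sbp) && !is.na(dbp)) {
      mbp <- (sbp + 2 * dbp) / 3
      src <- "sys_dia"
    } else src <- NA_character_
  }
  list(mbp = mbp, spo2 = g("SpO2"), mbp_source = src)
}

#' Process a per-second record stream into a timeline and alerts
#'
#' Runs the fuzzy engine once per record, producing a pre-diagnosis
#' timeline, and emits an alert whenever a patient's situation label
#' changes to a label whose urgency is not `"none"` (the stream start
#' counts as a transition). Repeat alerts for the same label within
#' `debounce_seconds` are suppressed. Records without usable inputs carry
#' the last label forward flagged `stale`; after `stale_gap_seconds` of
#' consecutive missing input a single sensor-fault notice is emitted.
#'
#' @param records Data.frame as returned by [read_records()] (any extra
#'   channels are ignored by the engine but preserved upstream).
#' @param engine A [fuzzy_engine()].
#' @param debounce_seconds Repeat-alert suppression window; default from
#'   the engine's monitoring config (0).
#' @param stale_gap_seconds Missing-input gap before a sensor-fault
#'   notice; default from the engine's monitoring config (30).
#' @return List with `timeline` (one row per record: inputs, score, label,
#'   urgency, stale flag) and `alerts` (label transitions with messages).
#' @export
process_stream <- function(records, engine,
                           debounce_seconds = NULL,
                           stale_gap_seconds = NULL) {
  stopifnot(inherits(engine, "fuzzy_engine"), is.data.frame(records))
  if (is.null(debounce_seconds))
    debounce_seconds <- engine$monitoring$debounce_seconds
  if (is.null(stale_gap_seconds))
    stale_gap_seconds <- engine$monitoring$stale_gap_seconds
  empty_timeline <- data.frame(
    patient_id = character(0), timestamp = as.POSIXct(character(0),
                                                      tz = "UTC"),
    mbp = numeric(0), spo2 = numeric(0), score = numeric(0),
    label = character(0), urgency = character(0), stale = logical(0),
    mbp_source = character(0), stringsAsFactors = FALSE)
  empty_alerts <- data.frame(
    patient_id = character(0), timestamp = as.POSIXct(character(0),
                                                      tz = "UTC"),
    label = character(0), message = character(0), urgency = character(0),
    previous_label = character(0), stringsAsFactors = FALSE)
  if (nrow(records) == 0L)
    return(list(timeline = empty_timeline, alerts = empty_alerts))
  records$timestamp <- parse_timestamp(records$timestamp)
  tl_rows <- list(); al_rows <- list()
  for (pid in unique(records$patient_id)) {
    rec <- records[records$patient_id == pid, , drop = FALSE]
    if (is.unsorted(rec$timestamp))
      stop("timestamps not non-decreasing for patient ", pid,
           call. = FALSE)
    last_label <- NA_character_; last_urgency <- NA_character_
    last_alert_time <- list()   # per label
    missing_since <- NULL; fault_notified <- FALSE
    for (i in seq_len(nrow(rec))) {
      row <- rec[i, , drop = FALSE]
      ins <- extract_inputs(row)
      ts <- row$timestamp
      usable <- !is.na(ins$mbp) && !is.na(ins$spo2)
      if (usable) {
        missing_since <- NULL; fault_notified <- FALSE
        pd <- infer(engine, ins$mbp, ins$spo2)
        tl_rows[[length(tl_rows) + 1L]] <- data.frame(
          patient_id = pid, timestamp = ts, mbp = ins$mbp,
          spo2 = ins$spo2, score = pd$score, label = pd$label,
          urgency = pd$urgency, stale = FALSE,
          mbp_source = ins$mbp_source, stringsAsFactors = FALSE)
        transition <- is.na(last_label) || pd$label != last_label
        if (transition && pd$urgency != "none") {
          prev_t <- last_alert_time[[pd$label]]
          if (is.null(prev_t) ||
              as.numeric(difftime(ts, prev_t, units = "secs")) >
                debounce_seconds) {
            al_rows[[length(al_rows) + 1L]] <- data.frame(
              patient_id = pid, timestamp = ts, label = pd$label,
              message = pd$message, urgency = pd$urgency,
              previous_label = if (is.na(last_label)) "" else last_label,
              stringsAsFactors = FALSE)
            last_alert_time[[pd$label]] <- ts
          }
        }
        last_label <- pd$label; last_urgency <- pd$urgency
      } else {
        if (is.null(missing_since)) missing_since <- ts
        tl_rows[[length(tl_rows) + 1L]] <- data.frame(
          patient_id = pid, timestamp = ts, mbp = NA_real_,
          spo2 = NA_real_, score = NA_real_, label = last_label,
          urgency = last_urgency, stale = TRUE,
          mbp_source = NA_character_, stringsAsFactors = FALSE)
        gap <- as.numeric(difftime(ts, missing_since, units = "secs"))
        if (!fault_notified && gap >= stale_gap_seconds) {
          al_rows[[length(al_rows) + 1L]] <- data.frame(
            patient_id = pid, timestamp = ts, label = "sensor_fault",
            message = paste0("No usable vital-sign input for ", gap,
                             " s; check sensors"),
            urgency = "medium",
            previous_label = if (is.na(last_label)) "" else last_label,
            stringsAsFactors = FALSE)
          fault_notified <- TRUE
        }
      }
    }
  }
  timeline <- if (length(tl_rows)) do.call(rbind, tl_rows) else
    empty_timeline
  alerts <- if (length(al_rows)) do.call(rbind, al_rows) else empty_alerts
  rownames(timeline) <- NULL; rownames(alerts) <- NULL
  list(timeline = timeline, alerts = alerts)
}

#' Write alerts as an append-friendly JSON Lines log
#'
#' One structured JSON object per line (patient id, ISO-8601 timestamp,
#' label, urgency, message, previous label), replayable and diffable:
#' identical input produces a byte-identical file.
#'
#' @param alerts Alerts data.frame from [process_stream()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_alert_log <- function(alerts, path) {
  stopifnot(is.data.frame(alerts))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(alerts) > 0L) {
    for (i in seq_len(nrow(alerts))) {
      rec <- list(patient_id = alerts$patient_id[i],
                  timestamp = format_timestamp(alerts$timestamp[i]),
                  label = alerts$label[i],
                  urgency = alerts$urgency[i],
                  message = alerts$message[i],
                  previous_label = alerts$previous_label[i])
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}

#' Write the pre-diagnosis timeline as CSV
#'
#' @param timeline Timeline data.frame from [process_stream()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_timeline <- function(timeline, path) {
  out <- timeline
  out$timestamp <- format_timestamp(out$timestamp)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
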