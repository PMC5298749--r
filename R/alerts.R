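# Range-based anomaly detection over vitals records: per-measurement
# min/max thresholds, an always-on fall alert, and JSON record output.

#' Default clinical threshold ranges
#'
#' Conventional adult resting ranges; every bound is configurable per
#' patient.
#'
#' @return Data frame `measurement, min, max` covering `temperature_c`
#'   (36--38 degC), `hr_bpm` (60--100), `spo2_pct` (94--100) and
#'   `respiration_bpm` (12--20).
#' @export
default_ranges <- function() {
  data.frame(
    measurement = c("temperature_c", "hr_bpm", "spo2_pct",
                    "respiration_bpm"),
    min = c(36, 60, 94, 12),
    max = c(38, 100, 100, 20))
}

#' Check a vitals record against threshold ranges
#'
#' Emits one alert per measurement present in the record and outside its
#' `[min, max]` range; a set fall flag always raises an alert regardless
#' of ranges. Absent fields and in-range values raise nothing;
#' measurements without a configured range are skipped with a warning.
#'
#' @param rec A [vitals_record()].
#' @param ranges Data frame `measurement, min, max` (all `min < max`),
#'   e.g. [default_ranges()].
#' @return Data frame of alert events: `patient_id, measurement, value,
#'   bound, limit, timestamp`; zero rows when everything is in range.
#' @export
check_record <- function(rec, ranges = default_ranges()) {
  stopifnot(inherits(rec, "vitals_record"), is.data.frame(ranges),
            all(c("measurement", "min", "max") %in% names(ranges)))
  if (any(ranges$min >= ranges$max)) stop("ranges must have min < max")
  out <- list()
  measured <- setdiff(names(rec), c("patient_id", "timestamp", "fall",
                                    "location", "gsr_ohms"))
  for (mm in measured) {
    v <- rec[[mm]]
    if (is.null(v) || is.na(v)) next
    row <- ranges[ranges$measurement == mm, , drop = FALSE]
    if (nrow(row) == 0L) {
      warning("no threshold range configured for ", mm, "; skipped")
      next
    }
    if (v < row$min) {
      out[[length(out) + 1L]] <- data.frame(
        patient_id = rec$patient_id, measurement = mm, value = v,
        bound = "min", limit = row$min, timestamp = rec$timestamp)
    } else if (v > row$max) {
      out[[length(out) + 1L]] <- data.frame(
        patient_id = rec$patient_id, measurement = mm, value = v,
        bound = "max", limit = row$max, timestamp = rec$timestamp)
    }
  }
  if (isTRUE(rec$fall))
    out[[length(out) + 1L]] <- data.frame(
      patient_id = rec$patient_id, measurement = "fall", value = 1,
      bound = "fall", limit = NA_real_, timestamp = rec$timestamp)
  if (length(out) == 0L)
    data.frame(patient_id = integer(), measurement = character(),
               value = numeric(), bound = character(), limit = numeric(),
               timestamp = numeric())
  else do.call(rbind, out)
}

# canonical key order of serialized records
.record_keys <- c("patient_id", "timestamp", "temperature_c", "hr_bpm",
                  "spo2_pct", "respiration_bpm", "gsr_ohms", "fall",
                  "location")

#' Serialize a vitals record to canonical JSON
#'
#' Fixed key order, ISO-8601 UTC timestamp, absent fields omitted (never
#' null-filled); [record_from_json()] is the exact inverse.
#'
#' @param rec A [vitals_record()].
#' @return A single JSON string.
#' @export
record_to_json <- function(rec) {
  stopifnot(inherits(rec, "vitals_record"))
  vals <- unclass(rec)
  num <- vals[!names(vals) %in% c("fall")]
  if (any(!vapply(num, function(v) is.logical(v) || is.finite(v),
                  logical(1))))
    stop("non-finite value: JSON cannot represent it")
  vals$timestamp <- format(as.POSIXct(vals$timestamp, origin = "1970-01-01",
                                      tz = "UTC"),
                           "%Y-%m-%dT%H:%M:%OS3Z")
  ordered <- vals[intersect(.record_keys, names(vals))]
  as.character(jsonlite::toJSON(ordered, auto_unbox = TRUE, digits = NA))
}

#' Parse a JSON vitals record
#'
#' @param json JSON string produced by [record_to_json()].
#' @return A [vitals_record()] equal to the one serialized.
#' @export
record_from_json <- function(json) {
  v <- jsonlite::fromJSON(json)
  ts <- as.numeric(as.POSIXct(v$timestamp, format = "%Y-%m-%dT%H:%M:%OS",
                              tz = "UTC"))
  vitals_record(patient_id = v$patient_id, timestamp = ts,
                temperature_c = v$temperature_c, hr_bpm = v$hr_bpm,
                spo2_pct = v$spo2_pct,
                respiration_bpm = v$respiration_bpm,
                gsr_ohms = v$gsr_ohms, fall = v$fall,
                location = v$location)
}

#' Append alert events to a JSON-lines log
#'
#' Local stand-in for the platform's push-notification path: each alert
#' is appended as one JSON object per line with a wall-clock `logged_at`
#' stamp, so pipeline latency can be measured from the log itself.
#'
#' @param alerts Data frame from [check_record()].
#' @param path Log file path (created if missing).
#' @return `path`, invisibly.
#' @export
append_alert_log <- function(alerts, path) {
  if (nrow(alerts) == 0L) return(invisible(path))
  con <- file(path, open = "a")
  on.exit(close(con))
  for (i in seq_len(nrow(alerts))) {
    rec <- as.list(alerts[i, ])
    rec$logged_at <- format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
    writeLines(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE,
                                             digits = NA)), con)
  }
  invisible(path)
}
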