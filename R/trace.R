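#' Construct a glucose trace
#'
#' A `glucose_trace` holds one patient's ordered, timestamped CGM readings in
#' mmol/L together with clipping flags and the device's nominal reporting
#' epoch. Readings are sorted by timestamp; duplicate timestamps keep the
#' first occurrence (with a warning when the discarded values differ).
#'
#' Monitored time is accounted per reading: each reading represents the
#' half-open interval `[t, t + nominal_epoch)`, so gaps contribute nothing
#' and `monitored_minutes(trace) == nominal_epoch * nrow(readings)`.
#'
#' @param readings data frame with columns `timestamp` (POSIXct or
#'   `YYYY-MM-DDTHH:MM` strings), `value` (glucose, mmol/L, > 0) and
#'   optionally `clipped` (`""`, `"low"` or `"high"`; default `""`).
#' @param patient_id opaque patient identifier.
#' @param device device generation label (`"G4"`, `"G6"`, or `"other"`).
#' @param nominal_epoch nominal sampling interval in minutes (default 5).
#' @return an object of class `glucose_trace`.
#' @export
glucose_trace <- function(readings, patient_id, device = "other",
                          nominal_epoch = 5) {
  stopifnot(is.character(patient_id) || is.factor(patient_id),
            length(patient_id) == 1L, nominal_epoch > 0)
  if (is.null(readings) || nrow(readings) == 0L) {
    readings <- data.frame(timestamp = as.POSIXct(character(), tz = "UTC"),
                           value = numeric(), clipped = character())
  }
  if (!inherits(readings$timestamp, "POSIXct")) {
    readings$timestamp <- parse_clock_time(as.character(readings$timestamp))
  }
  if (anyNA(readings$timestamp)) {
    stop("unparseable timestamp in readings for patient ", patient_id)
  }
  if (is.null(readings$clipped)) readings$clipped <- ""
  readings$clipped[is.na(readings$clipped)] <- ""
  if (!all(readings$clipped %in% c("", "low", "high"))) {
    stop("clipped flag must be one of '', 'low', 'high'")
  }
  if (any(!is.finite(readings$value)) || any(readings$value <= 0)) {
    stop("glucose values must be finite and positive (patient ",
         patient_id, ")")
  }
  o <- order(readings$timestamp)
  readings <- readings[o, c("timestamp", "value", "clipped"), drop = FALSE]
  dup <- duplicated(readings$timestamp)
  if (any(dup)) {
    conflicting <- sum(readings$value[dup] !=
                         readings$value[match(readings$timestamp[dup],
                                              readings$timestamp)])
    if (conflicting > 0L) {
      warning(sprintf(
        "patient %s: %d duplicate timestamp(s) with conflicting values; keeping first",
        patient_id, conflicting))
    }
    readings <- readings[!dup, , drop = FALSE]
  }
  rownames(readings) <- NULL
  structure(
    list(patient_id = as.character(patient_id),
         device = as.character(device),
         nominal_epoch = as.numeric(nominal_epoch),
         readings = readings),
    class = "glucose_trace")
}

#' Total monitored minutes of a trace
#'
#' Each reading contributes one nominal epoch; gaps contribute nothing.
#'
#' @param trace a `glucose_trace`.
#' @return monitored minutes (numeric scalar).
#' @export
monitored_minutes <- function(trace) {
  stopifnot(inherits(trace, "glucose_trace"))
  trace$nominal_epoch * nrow(trace$readings)
}

#' @export
print.glucose_trace <- function(x, ...) {
  n <- nrow(x$readings)
  cat(sprintf("<glucose_trace> patient %s (device %s): %d readings, %g monitored minutes\n",
              x$patient_id, x$device, n, monitored_minutes(x)))
  if (n > 0L) {
    cat(sprintf("  %s .. %s, glucose %.2f-%.2f mmol/L, %d clipped\n",
                format_clock_time(x$readings$timestamp[1L]),
                format_clock_time(x$readings$timestamp[n]),
                min(x$readings$value), max(x$readings$value),
                sum(x$readings$clipped != "")))
  }
  invisible(x)
}
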