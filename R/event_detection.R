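#' Detection configuration
#'
#' Hypoglycemia is defined as a glucose reading strictly below `threshold`
#' (default 3.5 mmol/L); a reading exactly at the threshold is not
#' hypoglycemic. Events are maximal runs of consecutive below-threshold
#' readings; an inter-reading gap greater than `max_gap_minutes` (default
#' 1.5 nominal epochs = 7.5 min) breaks a run, so unobserved time is never
#' counted as hypoglycemia. An event lasting strictly more than
#' `prolonged_minutes` (default 30) is prolonged; with 5-minute epochs that
#' means at least 35 minutes.
#'
#' @param threshold hypoglycemia threshold, mmol/L.
#' @param epoch_minutes minute value of one reading epoch.
#' @param max_gap_minutes largest inter-reading gap that still joins a run.
#' @param prolonged_minutes strict cutoff for a prolonged event.
#' @param floor,ceiling device reporting limits, mmol/L.
#' @return a `detection_config` list.
#' @export
detection_config <- function(threshold = 3.5, epoch_minutes = 5,
                             max_gap_minutes = 1.5 * epoch_minutes,
                             prolonged_minutes = 30,
                             floor = 2.2, ceiling = 22.2) {
  stopifnot(epoch_minutes > 0, max_gap_minutes >= epoch_minutes,
            threshold > 0, prolonged_minutes >= 0, floor > 0)
  structure(list(threshold = threshold, epoch_minutes = epoch_minutes,
                 max_gap_minutes = max_gap_minutes,
                 prolonged_minutes = prolonged_minutes,
                 floor = floor, ceiling = ceiling),
            class = "detection_config")
}

empty_events <- function() {
  data.frame(patient_id = character(), start = as.POSIXct(character(), tz = "UTC"),
             end = as.POSIXct(character(), tz = "UTC"), n_epochs = integer(),
             duration_min = numeric(), nadir_mmol_l = numeric(),
             nadir_clipped = logical())
}

#' Detect hypoglycemia events in a trace
#'
#' Segments the trace into maximal runs of consecutive readings with value
#' strictly below `config$threshold`, where consecutiveness additionally
#' requires the gap to the previous reading to be at most
#' `config$max_gap_minutes`. Every below-threshold reading belongs to
#' exactly one event. Duration is `n_epochs * epoch_minutes` (never
#' `end - start`, which would silently bridge gaps); the minimum event is a
#' single epoch. The nadir is the minimum glucose in the event;
#' `nadir_clipped` marks a nadir at the device floor, where the true
#' minimum is unknown.
#'
#' @param trace a [glucose_trace()] in mmol/L.
#' @param config a [detection_config()].
#' @return data frame of events with columns `patient_id`, `start`, `end`,
#'   `n_epochs`, `duration_min`, `nadir_mmol_l`, `nadir_clipped`.
#' @export
detect_events <- function(trace, config = detection_config()) {
  stopifnot(inherits(trace, "glucose_trace"), inherits(config, "detection_config"))
  r <- trace$readings
  idx <- which(r$value < config$threshold)
  if (length(idx) == 0L) return(empty_events())
  if (length(idx) > 1L) {
    gap_min <- as.numeric(difftime(r$timestamp[idx[-1L]],
                                   r$timestamp[idx[-length(idx)]],
                                   units = "mins"))
    new_run <- c(TRUE, diff(idx) != 1L | gap_min > config$max_gap_minutes)
  } else {
    new_run <- TRUE
  }
  run_id <- cumsum(new_run)
  events <- lapply(split(idx, run_id), function(ii) {
    vals <- r$value[ii]
    nadir <- min(vals)
    data.frame(
      patient_id = trace$patient_id,
      start = r$timestamp[ii[1L]],
      end = r$timestamp[ii[length(ii)]],
      n_epochs = length(ii),
      duration_min = length(ii) * config$epoch_minutes,
      nadir_mmol_l = nadir,
      nadir_clipped = any(r$clipped[ii][vals == nadir] == "low"))
  })
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}

#' Keep only prolonged events
#'
#' Retains events with `duration_min` strictly greater than
#' `config$prolonged_minutes`, preserving order.
#'
#' @param events event data frame from [detect_events()].
#' @param config a [detection_config()].
#' @return filtered event data frame.
#' @export
filter_prolonged <- function(events, config = detection_config()) {
  if (is.null(events) || nrow(events) == 0L) return(empty_events())
  events[events$duration_min > config$prolonged_minutes, , drop = FALSE]
}

#' Cohort-level event statistics
#'
#' Pools events and traces across a cohort: event count, hypoglycemic and
#' monitored minute totals, percent time hypoglycemic, duration and nadir
#' moments, per-patient event counts (patients with zero events included),
#' and prolonged-event summaries. SDs are sample SDs (n - 1).
#'
#' @param events event data frame pooled over the cohort (e.g. `rbind` of
#'   [detect_events()] outputs).
#' @param traces list of [glucose_trace()] objects; every event's patient
#'   must have a trace.
#' @param config a [detection_config()].
#' @return a `cohort_event_stats` list.
#' @export
cohort_event_stats <- function(events, traces, config = detection_config()) {
  stopifnot(is.list(traces), length(traces) > 0L)
  ids <- vapply(traces, function(tr) tr$patient_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate patient_id among traces")
  total_monitored <- sum(vapply(traces, monitored_minutes, numeric(1)))
  if (total_monitored <= 0) stop("zero monitored minutes: percent time undefined")
  if (is.null(events)) events <- empty_events()
  if (!all(events$patient_id %in% ids)) {
    stop("event patient(s) without a trace: ",
         paste(setdiff(unique(events$patient_id), ids), collapse = ", "))
  }
  counts <- table(factor(events$patient_id, levels = ids))
  per_patient <- as.integer(counts)
  names(per_patient) <- ids
  total_hypo <- sum(events$duration_min)
  prolonged <- filter_prolonged(events, config)
  sd_or_na <- function(x) if (length(x) > 1L) sd(x) else NA_real_
  structure(list(
    n_events = nrow(events),
    total_hypo_minutes = total_hypo,
    total_monitored_minutes = total_monitored,
    percent_time_hypo = 100 * total_hypo / total_monitored,
    mean_duration = if (nrow(events)) mean(events$duration_min) else NA_real_,
    sd_duration = sd_or_na(events$duration_min),
    mean_nadir = if (nrow(events)) mean(events$nadir_mmol_l) else NA_real_,
    sd_nadir = sd_or_na(events$nadir_mmol_l),
    per_patient_counts = per_patient,
    mean_events_per_patient = mean(per_patient),
    sd_events_per_patient = sd_or_na(per_patient),
    n_prolonged = nrow(prolonged),
    n_patients_with_prolonged = length(unique(prolonged$patient_id)),
    mean_prolonged_duration = if (nrow(prolonged)) mean(prolonged$duration_min) else NA_real_,
    mean_prolonged_nadir = if (nrow(prolonged)) mean(prolonged$nadir_mmol_l) else NA_real_),
    class = "cohort_event_stats")
}

#' @export
print.cohort_event_stats <- function(x, ...) {
  cat(sprintf("<cohort_event_stats> %d events over %d patients\n",
              x$n_events, length(x$per_patient_counts)))
  cat(sprintf("  time hypoglycemic: %g of %g minutes (%.1f%%)\n",
              x$total_hypo_minutes, x$total_monitored_minutes,
              x$percent_time_hypo))
  if (x$n_events > 0L) {
    cat(sprintf("  duration %.0f (SD %.0f) min; nadir %.1f (SD %.2f) mmol/L\n",
                x$mean_duration, x$sd_duration, x$mean_nadir, x$sd_nadir))
    cat(sprintf("  events/patient %.1f (SD %.1f); %d prolonged (>%s min) from %d patient(s)\n",
                x$mean_events_per_patient, x$sd_events_per_patient,
                x$n_prolonged, "30", x$n_patients_with_prolonged))
  }
  invisible(x)
}

#' Write events in the canonical CSV layout
#'
#' Columns `patient_id,start,end,n_epochs,duration_min,nadir_mmol_l,
#' nadir_clipped` with ISO-8601 minute timestamps.
#'
#' @param events event data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  out <- events
  out$start <- format_clock_time(out$start)
  out$end <- format_clock_time(out$end)
  out$nadir_mmol_l <- sprintf("%.2f", out$nadir_mmol_l)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
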