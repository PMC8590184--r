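#' Clock-time window
#'
#' A half-open window `[start_hour:00, end_hour:00)` on the 24-hour clock.
#' Windows may cross midnight (`start_hour > end_hour`), e.g. 18:00-01:00.
#' `end_hour = 24` (or 0) closes the window at midnight.
#'
#' @param start_hour integer 0-23.
#' @param end_hour integer 0-24.
#' @param label human-readable label.
#' @return a `clock_window` list with the covered `hours` and `width_hours`.
#' @examples
#' clock_window(3, 7, "early hours")   # 03:00-07:00, width 4 h
#' clock_window(18, 1, "evening")      # 18:00-01:00 across midnight, width 7 h
#' @export
clock_window <- function(start_hour, end_hour, label = "") {
  stopifnot(start_hour %in% 0:23, end_hour %in% 0:24)
  e <- end_hour %% 24
  if (start_hour == e) {
    hours <- 0:23                      # full day
  } else if (start_hour < e) {
    hours <- start_hour:(e - 1L)
  } else {
    hours <- c(start_hour:23, if (e > 0) 0:(e - 1L))
  }
  structure(list(start_hour = start_hour, end_hour = end_hour,
                 label = label, hours = as.integer(hours),
                 width_hours = length(hours)),
            class = "clock_window")
}

#' @export
print.clock_window <- function(x, ...) {
  cat(sprintf("<clock_window> %s[%02d:00, %02d:00) width %d h\n",
              if (nzchar(x$label)) paste0(x$label, " ") else "",
              x$start_hour, x$end_hour %% 24, x$width_hours))
  invisible(x)
}

#' Hour-of-day profile of monitored and hypoglycemic minutes
#'
#' Each reading contributes one epoch of monitored minutes to the hour bin
#' of its timestamp (no splitting across bins: an epoch starting 03:55 is
#' credited wholly to hour 3), and to the hypoglycemic minutes of that bin
#' iff its value is strictly below the threshold. `event_starts[h]` counts
#' events whose first below-threshold reading falls in hour `h`. Binning is
#' by wall clock.
#'
#' @param traces list of [glucose_trace()] objects (a single trace is
#'   accepted).
#' @param events pooled event data frame from [detect_events()], consistent
#'   with `traces` and `config`; pass `NULL` to skip start counting.
#' @param config a [detection_config()].
#' @return an `hourly_profile` data frame with columns `hour`,
#'   `monitored_min`, `hypo_min`, `percent`, `event_starts`.
#' @export
minutes_by_hour <- function(traces, events = NULL,
                            config = detection_config()) {
  if (inherits(traces, "glucose_trace")) traces <- list(traces)
  stopifnot(length(traces) > 0L)
  monitored <- hypo <- numeric(24)
  for (tr in traces) {
    stopifnot(inherits(tr, "glucose_trace"))
    if (nrow(tr$readings) == 0L) next
    h <- clock_hour(tr$readings$timestamp)
    monitored <- monitored +
      tabulate(h + 1L, 24L) * tr$nominal_epoch
    below <- tr$readings$value < config$threshold
    hypo <- hypo + tabulate(h[below] + 1L, 24L) * tr$nominal_epoch
  }
  starts <- integer(24)
  if (!is.null(events) && nrow(events) > 0L) {
    starts <- tabulate(clock_hour(events$start) + 1L, 24L)
  }
  out <- data.frame(hour = 0:23, monitored_min = monitored, hypo_min = hypo,
                    percent = ifelse(monitored > 0, 100 * hypo / monitored, NA_real_),
                    event_starts = starts)
  class(out) <- c("hourly_profile", "data.frame")
  out
}

#' Summarise a clock-time window against an hourly profile
#'
#' Computes inside/outside monitored and hypoglycemic minutes, percent time
#' hypoglycemic inside and outside, the share of all hypoglycemic minutes
#' falling inside the window, the share expected under an even distribution
#' (100 x width / 24), and the risk ratio (inside percent / outside
#' percent, `NA` when undefined).
#'
#' @param profile an `hourly_profile` from [minutes_by_hour()].
#' @param window a [clock_window()].
#' @return a `window_summary` list.
#' @export
window_summary <- function(profile, window) {
  stopifnot(inherits(profile, "hourly_profile"), inherits(window, "clock_window"))
  inside <- profile$hour %in% window$hours
  window_summary_from_counts(
    inside_monitored = sum(profile$monitored_min[inside]),
    inside_hypo = sum(profile$hypo_min[inside]),
    outside_monitored = sum(profile$monitored_min[!inside]),
    outside_hypo = sum(profile$hypo_min[!inside]),
    window = window)
}

#' @rdname window_summary
#' @param inside_monitored,inside_hypo,outside_monitored,outside_hypo
#'   minute counts, e.g. taken from a published table.
#' @export
window_summary_from_counts <- function(inside_monitored, inside_hypo,
                                       outside_monitored, outside_hypo,
                                       window) {
  stopifnot(inherits(window, "clock_window"),
            inside_hypo <= inside_monitored, outside_hypo <= outside_monitored,
            inside_hypo >= 0, outside_hypo >= 0)
  if (inside_monitored <= 0) stop("no monitored minutes inside window: percents undefined")
  total_hypo <- inside_hypo + outside_hypo
  inside_pct <- 100 * inside_hypo / inside_monitored
  outside_pct <- if (outside_monitored > 0) 100 * outside_hypo / outside_monitored else NA_real_
  structure(list(
    window = window,
    inside_monitored = inside_monitored, inside_hypo = inside_hypo,
    outside_monitored = outside_monitored, outside_hypo = outside_hypo,
    inside_percent = inside_pct,
    outside_percent = outside_pct,
    hypo_share_inside = if (total_hypo > 0) 100 * inside_hypo / total_hypo else NA_real_,
    expected_share = 100 * window$width_hours / 24,
    risk_ratio = if (!is.na(outside_pct) && outside_pct > 0) inside_pct / outside_pct else NA_real_),
    class = "window_summary")
}

#' @export
print.window_summary <- function(x, ...) {
  w <- x$window
  cat(sprintf("<window_summary> %s[%02d:00, %02d:00)\n",
              if (nzchar(w$label)) paste0(w$label, " ") else "",
              w$start_hour, w$end_hour %% 24))
  cat(sprintf("  inside:  %g/%g min hypoglycemic (%.1f%%)\n",
              x$inside_hypo, x$inside_monitored, x$inside_percent))
  cat(sprintf("  outside: %g/%g min hypoglycemic (%.1f%%)\n",
              x$outside_hypo, x$outside_monitored, x$outside_percent))
  cat(sprintf("  share of hypo minutes inside: %.2f%% (expected %.1f%%); risk ratio %.2f\n",
              x$hypo_share_inside, x$expected_share, x$risk_ratio))
  invisible(x)
}

#' Re-run detection and windowing over a set of thresholds
#'
#' For each threshold the events are re-detected and the window summarised.
#' Total hypoglycemic minutes are non-increasing as the threshold
#' decreases (event counts need not be monotone, since runs can split).
#'
#' @param traces list of [glucose_trace()] objects.
#' @param thresholds mmol/L values, each strictly above the device floor.
#' @param window a [clock_window()].
#' @param config a [detection_config()]; its `threshold` field is replaced
#'   per sweep point.
#' @return a `threshold_sweep` list: `table` (data frame with one row per
#'   threshold) and `summaries` (named list of `window_summary`).
#' @export
threshold_sweep <- function(traces, thresholds, window,
                            config = detection_config()) {
  if (inherits(traces, "glucose_trace")) traces <- list(traces)
  stopifnot(length(thresholds) > 0L)
  if (any(thresholds <= config$floor)) {
    stop("threshold at or below the device floor (", config$floor,
         " mmol/L): clipped readings would be ambiguous")
  }
  thresholds <- sort(thresholds, decreasing = TRUE)
  rows <- list(); summaries <- list()
  prev_minutes <- Inf
  for (th in thresholds) {
    cfg <- config
    cfg$threshold <- th
    events <- do.call(rbind, lapply(traces, detect_events, config = cfg))
    if (is.null(events)) events <- empty_events()
    profile <- minutes_by_hour(traces, events, cfg)
    ws <- window_summary(profile, window)
    total <- sum(profile$hypo_min)
    if (total > prev_minutes + 1e-9) {
      stop("internal error: hypo minutes increased as threshold decreased")
    }
    prev_minutes <- total
    key <- sprintf("%.1f", th)
    summaries[[key]] <- ws
    rows[[key]] <- data.frame(
      threshold = th, n_events = nrow(events), total_hypo_minutes = total,
      inside_hypo = ws$inside_hypo, inside_percent = ws$inside_percent,
      outside_hypo = ws$outside_hypo, outside_percent = ws$outside_percent,
      hypo_share_inside = ws$hypo_share_inside)
  }
  structure(list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 summaries = summaries, window = window),
            class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat("<threshold_sweep> window ")
  print(x$window)
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write an hourly profile as CSV
#'
#' Columns `hour,monitored_min,hypo_min,percent,event_starts`.
#'
#' @param profile an `hourly_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  write.csv(as.data.frame(profile), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
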