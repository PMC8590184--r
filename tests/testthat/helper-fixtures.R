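# fixture builders shared across tests; everything generated in code

epoch_times <- function(n, start = "2020-01-01T00:00", by_min = 5) {
  t0 <- as.POSIXct(sub("T", " ", start), tz = "UTC")
  t0 + (seq_len(n) - 1) * 60 * by_min
}

make_trace <- function(values, start = "2020-01-01T00:00", by_min = 5,
                       patient_id = "P1", clipped = NULL) {
  df <- data.frame(timestamp = epoch_times(length(values), start, by_min),
                   value = values)
  if (!is.null(clipped)) df$clipped <- clipped
  glucose_trace(df, patient_id = patient_id)
}

# random trace with gaps: n readings, some epochs skipped, values around 4
random_trace <- function(n, patient_id = "P1", p_gap = 0.15) {
  ts <- epoch_times(3 * n + 20)
  keep <- runif(length(ts)) >= p_gap
  ts <- ts[keep][seq_len(n)]
  make_from_ts(ts, round(runif(n, 2.5, 5.5), 2), patient_id)
}

make_from_ts <- function(ts, values, patient_id = "P1") {
  glucose_trace(data.frame(timestamp = ts, value = values),
                patient_id = patient_id)
}

# brute-force oracle: enumerate maximal below-threshold runs by walking the
# readings one by one (independent of the vectorized implementation)
brute_force_events <- function(trace, config = detection_config()) {
  r <- trace$readings
  runs <- list()
  current <- integer(0)
  for (i in seq_len(nrow(r))) {
    if (r$value[i] < config$threshold) {
      if (length(current) > 0) {
        gap <- as.numeric(difftime(r$timestamp[i],
                                   r$timestamp[current[length(current)]],
                                   units = "mins"))
        joined <- (i - current[length(current)] == 1) &&
          gap <= config$max_gap_minutes
      } else joined <- FALSE
      if (joined) current <- c(current, i)
      else {
        if (length(current)) runs[[length(runs) + 1]] <- current
        current <- i
      }
    } else {
      if (length(current)) runs[[length(runs) + 1]] <- current
      current <- integer(0)
    }
  }
  if (length(current)) runs[[length(runs) + 1]] <- current
  runs
}

# brute-force Mann-Whitney U for x: pair counting
brute_force_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# ages of the 23-patient HI cohort characteristics table
hi_ages <- c(88, 8, 92, 34, 37, 119, 58, 190, 141, 132, 2, 36, 51, 36, 17,
             3, 63, 10, 193, 1, 3, 1, 3)
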