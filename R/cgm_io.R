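#' Read a CGM trace from CSV
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`normalized`}{the package's canonical dialect, header
#'     `patient_id,timestamp,glucose_mmol_l,clipped` with ISO-8601 local
#'     timestamps (`YYYY-MM-DDTHH:MM`), glucose in mmol/L to 2 decimals and
#'     `clipped` one of `""`, `"low"`, `"high"`.}
#'   \item{`clarity`}{a Dexcom-CLARITY-style export with columns
#'     `Timestamp (YYYY-MM-DDThh:mm:ss)`, `Event Type` and
#'     `Glucose Value (mg/dL)` (or `(mmol/L)`). Only `EGV` (estimated glucose
#'     value) rows are kept; calibration and alert rows are dropped. Textual
#'     `Low`/`High` values are imputed at the device floor/ceiling and
#'     flagged as clipped.}
#' }
#'
#' All values are normalized to mmol/L (factor 18.016 mg/dL per mmol/L) and
#' stored to 2 decimals. Readings are sorted and deduplicated (first kept).
#'
#' @param path CSV file path.
#' @param dialect `"normalized"` or `"clarity"`.
#' @param units `"mmol_L"`, `"mg_dL"`, or `"auto"` (infer from the glucose
#'   column header for the clarity dialect; the normalized dialect is always
#'   mmol/L).
#' @param patient_id patient identifier; for the normalized dialect defaults
#'   to the file's `patient_id` column (which must then be single-valued).
#' @param device device label stored on the trace.
#' @param floor,ceiling device reporting limits in mmol/L used to impute
#'   textual `Low`/`High` readings (defaults 2.2 and 22.2).
#' @param nominal_epoch nominal sampling interval in minutes.
#' @return a [glucose_trace()].
#' @export
parse_cgm_csv <- function(path, dialect = c("normalized", "clarity"),
                          units = c("auto", "mmol_L", "mg_dL"),
                          patient_id = NULL, device = "other",
                          floor = 2.2, ceiling = 22.2, nominal_epoch = 5) {
  dialect <- match.arg(dialect)
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (nrow(raw) == 0L) stop("empty CGM file: ", path)

  if (dialect == "normalized") {
    need <- c("patient_id", "timestamp", "glucose_mmol_l", "clipped")
    if (!all(need %in% names(raw))) {
      stop("normalized dialect requires columns: ", paste(need, collapse = ", "))
    }
    if (is.null(patient_id)) {
      ids <- unique(raw$patient_id)
      if (length(ids) != 1L) stop("file contains multiple patient_ids; pass patient_id")
      patient_id <- ids
    } else {
      raw <- raw[raw$patient_id == patient_id, , drop = FALSE]
      if (nrow(raw) == 0L) stop("no rows for patient ", patient_id)
    }
    if (units == "mg_dL") stop("normalized dialect is defined in mmol/L")
    value_txt <- raw$glucose_mmol_l
    clipped <- raw$clipped
    ts_txt <- raw$timestamp
    in_mgdl <- FALSE
  } else {
    ts_col <- grep("^Timestamp", names(raw), value = TRUE)
    gl_col <- grep("^Glucose Value", names(raw), value = TRUE)
    if (length(ts_col) != 1L || length(gl_col) != 1L ||
        !"Event Type" %in% names(raw)) {
      stop("clarity dialect requires 'Timestamp (...)', 'Event Type' and 'Glucose Value (...)' columns")
    }
    raw <- raw[raw$`Event Type` == "EGV", , drop = FALSE]
    if (nrow(raw) == 0L) stop("no EGV rows in ", path)
    in_mgdl <- switch(units,
      auto = grepl("mg/dL", gl_col, fixed = TRUE),
      mg_dL = TRUE,
      mmol_L = FALSE)
    if (units == "auto" && !grepl("mg/dL|mmol/L", gl_col)) {
      stop("cannot infer units from column '", gl_col, "'")
    }
    value_txt <- raw[[gl_col]]
    clipped <- rep("", nrow(raw))
    ts_txt <- raw[[ts_col]]
    if (is.null(patient_id)) stop("clarity dialect requires patient_id")
  }

  low <- trimws(value_txt) %in% c("Low", "LOW", "low")
  high <- trimws(value_txt) %in% c("High", "HIGH", "high")
  value <- suppressWarnings(as.numeric(value_txt))
  bad <- !(low | high) & !is.finite(value)
  if (any(bad)) {
    stop("unparseable glucose value at row ", which(bad)[1L], ": '",
         value_txt[which(bad)[1L]], "'")
  }
  if (in_mgdl) value <- mgdl_to_mmol(value)
  value[low] <- floor
  value[high] <- ceiling
  clipped[low] <- "low"
  clipped[high] <- "high"

  ts <- parse_clock_time(ts_txt)
  if (anyNA(ts)) {
    stop("unparseable timestamp at row ", which(is.na(ts))[1L], ": '",
         ts_txt[which(is.na(ts))[1L]], "'")
  }

  glucose_trace(
    data.frame(timestamp = ts, value = round(value, 2), clipped = clipped),
    patient_id = patient_id, device = device, nominal_epoch = nominal_epoch)
}

#' Write a trace in the normalized CSV dialect
#'
#' Writing and re-parsing reproduces the trace exactly: timestamps to the
#' minute, glucose to 2 decimals, clip flags preserved.
#'
#' @param trace a [glucose_trace()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cgm_csv <- function(trace, path) {
  stopifnot(inherits(trace, "glucose_trace"))
  out <- data.frame(
    patient_id = rep(trace$patient_id, nrow(trace$readings)),
    timestamp = format_clock_time(trace$readings$timestamp),
    glucose_mmol_l = sprintf("%.2f", trace$readings$value),
    clipped = trace$readings$clipped)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read cohort metadata
#'
#' Expects the header `patient_id,diagnosis,sex,age_months,mutation,hi_type,
#' surgery,medication,location` (an optional `months_since_diagnosis` column
#' is carried through). `medication` is a `;`-separated list of treatment
#' labels, empty for off-medication patients. For IKH patients `hi_type` and
#' `surgery` must be `n/a`.
#'
#' @param path metadata CSV path.
#' @return data frame of patient records.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  md <- read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c("patient_id", "diagnosis", "sex", "age_months", "mutation",
            "hi_type", "surgery", "medication", "location")
  if (!all(need %in% names(md))) {
    stop("metadata requires columns: ", paste(need, collapse = ", "))
  }
  md$age_months <- as.integer(md$age_months)
  if ("months_since_diagnosis" %in% names(md)) {
    md$months_since_diagnosis <- as.numeric(md$months_since_diagnosis)
  }
  bad <- md$diagnosis == "IKH" & (md$hi_type != "n/a" | md$surgery != "n/a")
  if (any(bad)) {
    stop("IKH patients must have hi_type and surgery 'n/a': ",
         paste(md$patient_id[bad], collapse = ", "))
  }
  md
}

#' Read exclusion intervals
#'
#' Header `patient_id,start,end,reason`; intervals are half-open
#' `[start, end)` local clock times with `start < end`.
#'
#' @param path exclusions CSV path.
#' @return data frame with POSIXct `start`/`end`.
#' @export
read_exclusions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ex <- read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c("patient_id", "start", "end", "reason")
  if (!all(need %in% names(ex))) {
    stop("exclusions require columns: ", paste(need, collapse = ", "))
  }
  ex$start <- parse_clock_time(ex$start)
  ex$end <- parse_clock_time(ex$end)
  if (anyNA(ex$start) || anyNA(ex$end)) stop("unparseable exclusion timestamp")
  if (any(ex$start >= ex$end)) stop("exclusion intervals require start < end")
  ex
}

#' Remove readings inside exclusion intervals
#'
#' Used e.g. to delete data recorded during an in-hospital controlled fast.
#' Readings whose timestamp falls inside any half-open `[start, end)`
#' interval for this patient are dropped; ordering is preserved. An empty
#' exclusion list is the identity. Exclusion never increases monitored
#' minutes, and disjoint exclusions compose in any order.
#'
#' @param trace a [glucose_trace()].
#' @param exclusions data frame as from [read_exclusions()]; rows for other
#'   patients are ignored.
#' @return the filtered `glucose_trace`.
#' @export
exclude_intervals <- function(trace, exclusions) {
  stopifnot(inherits(trace, "glucose_trace"))
  if (is.null(exclusions) || nrow(exclusions) == 0L) return(trace)
  ex <- exclusions[exclusions$patient_id == trace$patient_id, , drop = FALSE]
  if (nrow(ex) == 0L) return(trace)
  if (any(ex$start >= ex$end)) stop("exclusion intervals require start < end")
  keep <- rep(TRUE, nrow(trace$readings))
  ts <- trace$readings$timestamp
  for (i in seq_len(nrow(ex))) {
    keep <- keep & !(ts >= ex$start[i] & ts < ex$end[i])
  }
  trace$readings <- trace$readings[keep, , drop = FALSE]
  rownames(trace$readings) <- NULL
  trace
}

#' Demographic summary of a cohort
#'
#' Per-diagnosis counts by sex and mean/SD of age (months) and, when a
#' `months_since_diagnosis` column is present, of time since diagnosis.
#' Records with missing age are excluded from the mean with a message; the
#' SD of a single observation is reported as 0 with a warning so that
#' summary tables stay total-safe.
#'
#' @param records data frame of patient records (see [read_metadata()]).
#' @return data frame, one row per diagnosis group.
#' @export
cohort_summary <- function(records) {
  if (is.null(records) || nrow(records) == 0L) stop("empty cohort")
  safe_sd <- function(x) {
    if (length(x) <= 1L) {
      warning("SD of a single observation reported as 0")
      return(0)
    }
    sd(x)
  }
  groups <- unique(records$diagnosis)
  out <- lapply(groups, function(g) {
    r <- records[records$diagnosis == g, , drop = FALSE]
    age <- r$age_months
    n_missing <- sum(is.na(age))
    if (n_missing > 0L) {
      message(sprintf("%s: %d record(s) with missing age excluded from mean",
                      g, n_missing))
      age <- age[!is.na(age)]
    }
    row <- data.frame(
      diagnosis = g,
      n = nrow(r),
      n_male = sum(r$sex == "male"),
      n_female = sum(r$sex == "female"),
      mean_age_months = mean(age),
      sd_age_months = safe_sd(age))
    if ("months_since_diagnosis" %in% names(r)) {
      tsd <- r$months_since_diagnosis[!is.na(r$months_since_diagnosis)]
      row$mean_months_since_diagnosis <- if (length(tsd)) mean(tsd) else NA_real_
      row$sd_months_since_diagnosis <- if (length(tsd)) safe_sd(tsd) else NA_real_
    }
    row
  })
  do.call(rbind, out)
}
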