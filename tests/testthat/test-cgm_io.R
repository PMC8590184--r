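test_that("normalized CSV parsing builds the trace and accounts minutes", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,timestamp,glucose_mmol_l,clipped",
               "P1,2020-01-01T08:00,5.00,",
               "P1,2020-01-01T08:05,3.40,",
               "P1,2020-01-01T08:10,5.20,"), path)
  tr <- parse_cgm_csv(path, dialect = "normalized")
  expect_s3_class(tr, "glucose_trace")
  expect_equal(nrow(tr$readings), 3L)
  expect_equal(monitored_minutes(tr), 15)
  expect_equal(tr$readings$value, c(5.0, 3.4, 5.2))
})

test_that("textual Low/High rows are imputed at the device limits and flagged", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Timestamp (YYYY-MM-DDThh:mm:ss),Event Type,Glucose Value (mmol/L)",
               "2020-01-01T02:00:00,EGV,Low",
               "2020-01-01T02:05:00,EGV,3.40",
               "2020-01-01T02:10:00,EGV,High",
               "2020-01-01T02:15:00,Calibration,4.00"), path)
  tr <- parse_cgm_csv(path, dialect = "clarity", patient_id = "P1")
  expect_equal(nrow(tr$readings), 3L)  # calibration row dropped
  expect_equal(tr$readings$value[1], 2.2)
  expect_equal(tr$readings$clipped, c("low", "", "high"))
  expect_equal(tr$readings$value[3], 22.2)
})

test_that("mg/dL CLARITY values are converted to mmol/L", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Timestamp (YYYY-MM-DDThh:mm:ss),Event Type,Glucose Value (mg/dL)",
               "2020-01-01T02:00:00,EGV,63",
               "2020-01-01T02:05:00,EGV,99"), path)
  tr <- parse_cgm_csv(path, dialect = "clarity", patient_id = "P1")
  expect_equal(tr$readings$value[1], 3.5)  # the clinical 63 mg/dL pairing
  expect_equal(tr$readings$value[2], 5.5)  # 99 / 18.016 = 5.4951
})

test_that("parser errors name the offending row", {
  bad_ts <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,timestamp,glucose_mmol_l,clipped",
               "P1,2020-01-01T08:00,5.00,",
               "P1,not-a-time,5.00,"), bad_ts)
  expect_error(parse_cgm_csv(bad_ts, "normalized"), "row 2")
  bad_val <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,timestamp,glucose_mmol_l,clipped",
               "P1,2020-01-01T08:00,oops,"), bad_val)
  expect_error(parse_cgm_csv(bad_val, "normalized"), "row 1")
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("patient_id,timestamp,glucose_mmol_l,clipped", empty)
  expect_error(parse_cgm_csv(empty, "normalized"), "empty")
})

test_that("normalized CSV round-trips exactly", {
  set.seed(11)
  tr <- make_trace(round(runif(50, 2.2, 9), 2),
                   clipped = sample(c("", "", "", "low"), 50, replace = TRUE))
  # clipped=low must sit at the floor by convention
  tr$readings$value[tr$readings$clipped == "low"] <- 2.2
  path <- withr::local_tempfile(fileext = ".csv")
  write_cgm_csv(tr, path)
  back <- parse_cgm_csv(path, dialect = "normalized")
  expect_equal(back$readings$timestamp, tr$readings$timestamp)
  expect_equal(back$readings$value, tr$readings$value)
  expect_equal(back$readings$clipped, tr$readings$clipped)
})

test_that("unit conversion is an involution to 2 decimals", {
  x <- round(seq(2.2, 22.2, by = 0.37), 2)
  expect_equal(mgdl_to_mmol(mmol_to_mgdl(x)), x)
})

test_that("duplicate timestamps keep the first value with a warning on conflict", {
  ts <- epoch_times(3)
  df <- data.frame(timestamp = ts[c(1, 2, 2, 3)], value = c(5, 4, 6, 5))
  expect_warning(tr <- glucose_trace(df, "P1"), "conflicting")
  expect_equal(nrow(tr$readings), 3L)
  expect_equal(tr$readings$value[2], 4)
})

test_that("exclusion intervals drop the covered half-open range", {
  tr <- make_trace(rep(5, 12))
  # identity on empty list
  expect_equal(exclude_intervals(tr, NULL)$readings, tr$readings)
  # whole-trace exclusion annihilates
  all_ex <- data.frame(patient_id = "P1",
                       start = epoch_times(1) - 60,
                       end = epoch_times(13)[13], reason = "fast")
  expect_equal(monitored_minutes(exclude_intervals(tr, all_ex)), 0)
  # readings 4-6 removed: [00:15, 00:30) covers epochs at 15, 20, 25
  part <- data.frame(patient_id = "P1",
                     start = as.POSIXct("2020-01-01 00:15", tz = "UTC"),
                     end = as.POSIXct("2020-01-01 00:30", tz = "UTC"),
                     reason = "fast")
  out <- exclude_intervals(tr, part)
  expect_equal(nrow(out$readings), 9L)
  expect_equal(monitored_minutes(out), 45)
  # half-open: a reading exactly at end survives
  expect_true(as.POSIXct("2020-01-01 00:30", tz = "UTC") %in%
                out$readings$timestamp)
  # other patients' exclusions are ignored
  other <- part; other$patient_id <- "P2"
  expect_equal(nrow(exclude_intervals(tr, other)$readings), 12L)
})

test_that("disjoint exclusions compose commutatively and never add minutes", {
  set.seed(21)
  for (i in 1:5) {
    tr <- random_trace(60)
    e1 <- data.frame(patient_id = "P1",
                     start = as.POSIXct("2020-01-01 00:30", tz = "UTC"),
                     end = as.POSIXct("2020-01-01 01:00", tz = "UTC"),
                     reason = "a")
    e2 <- data.frame(patient_id = "P1",
                     start = as.POSIXct("2020-01-01 02:00", tz = "UTC"),
                     end = as.POSIXct("2020-01-01 02:30", tz = "UTC"),
                     reason = "b")
    ab <- exclude_intervals(exclude_intervals(tr, e1), e2)
    ba <- exclude_intervals(exclude_intervals(tr, e2), e1)
    expect_equal(ab$readings, ba$readings)
    expect_lte(monitored_minutes(ab), monitored_minutes(tr))
  }
})

test_that("cohort summary reproduces the published HI mean age", {
  records <- data.frame(patient_id = sprintf("H%02d", seq_along(hi_ages)),
                        diagnosis = "HI",
                        sex = "male",
                        age_months = hi_ages)
  s <- cohort_summary(records)
  expect_equal(round(s$mean_age_months), 57)
  expect_equal(s$n, 23L)
})

test_that("cohort summary edge cases: single record and symmetric ages", {
  one <- data.frame(patient_id = "X", diagnosis = "HI", sex = "female",
                    age_months = 10L)
  expect_warning(s1 <- cohort_summary(one), "single observation")
  expect_equal(s1$mean_age_months, 10)
  expect_equal(s1$sd_age_months, 0)
  three <- data.frame(patient_id = c("A", "B", "C"), diagnosis = "IKH",
                      sex = "male", age_months = c(1L, 2L, 3L))
  expect_equal(cohort_summary(three)$mean_age_months, 2)
  # missing ages excluded with a message
  withmiss <- rbind(three, data.frame(patient_id = "D", diagnosis = "IKH",
                                      sex = "male", age_months = NA_integer_))
  expect_message(s2 <- cohort_summary(withmiss), "missing age")
  expect_equal(s2$mean_age_months, 2)
  expect_equal(s2$n, 4L)
})

test_that("metadata reader enforces the IKH n/a invariant", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,diagnosis,sex,age_months,mutation,hi_type,surgery,medication,location",
               "P1,IKH,male,40,not-done,diffuse,none,,outpatient"), path)
  expect_error(read_metadata(path), "n/a")
  ok <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,diagnosis,sex,age_months,mutation,hi_type,surgery,medication,location",
               "P1,IKH,male,40,not-done,n/a,n/a,,outpatient",
               "P2,HI,female,8,positive:ABCC8,focal,lesionectomy,octreotide,inpatient"),
             ok)
  md <- read_metadata(ok)
  expect_equal(md$age_months, c(40L, 8L))
})
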