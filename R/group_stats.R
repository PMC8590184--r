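#' Pearson chi-square test on a 2x2 table
#'
#' Closed-form Pearson statistic
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with 1 degree of freedom;
#' optionally the Yates continuity-corrected variant. By default no
#' correction is applied: the tables here count minutes, where the
#' correction is immaterial. The p-value is two-sided from the chi-square
#' distribution.
#'
#' @param a,b,c,d non-negative cell counts; rows are the two groups (or
#'   inside/outside a window), columns hypoglycemic / not-hypoglycemic
#'   minutes. Alternatively pass a 2x2 matrix as `a`.
#' @param correction apply the Yates continuity correction.
#' @return a `test_result` list: `statistic`, `df`, `p_value`, `method`,
#'   `notes`.
#' @export
pearson_chi2_2x2 <- function(a, b = NULL, c = NULL, d = NULL,
                             correction = FALSE) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2L))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  cells <- as.numeric(c(a, b, c, d))   # doubles: minute counts overflow ints
  stopifnot(length(cells) == 4L, all(is.finite(cells)), all(cells >= 0))
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  n <- sum(cells)
  if (n <= 0) stop("empty table")
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0) stop("degenerate row margin (all-zero row)")
  if (c1 == 0 || c2 == 0) stop("degenerate column margin (all-zero column)")
  num <- abs(a * d - b * c)
  if (correction) num <- max(0, num - n / 2)
  stat <- n * num^2 / (r1 * r2 * c1 * c2)
  structure(list(statistic = stat, df = 1L,
                 p_value = pchisq(stat, df = 1, lower.tail = FALSE),
                 method = "pearson_chi2",
                 notes = if (correction) "Yates continuity correction" else ""),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic %.4g%s, p = %.3g%s\n",
              x$method, x$statistic,
              if (!is.null(x$df) && !is.na(x$df)) sprintf(" (df %d)", x$df) else "",
              x$p_value,
              if (nzchar(x$notes)) paste0(" [", x$notes, "]") else ""))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' U is the number of pairs with `x_i > y_j` plus half the ties (so
#' complete separation with all `x < y` gives U = 0, and
#' `U_x + U_y = n1 * n2`). For `min(n1, n2) <= 8` the two-sided p-value is
#' computed by exact enumeration of all assignments of the pooled values to
#' the two groups (valid under ties); otherwise the tie-corrected normal
#' approximation is used. If every pooled value is identical the test is
#' degenerate and p = 1 is returned with a note.
#'
#' @param x,y numeric samples, both nonempty.
#' @return a `test_result` with `statistic` = U (for `x`).
#' @export
mann_whitney_u <- function(x, y) {
  stopifnot(length(x) > 0L, length(y) > 0L,
            all(is.finite(x)), all(is.finite(y)))
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(pooled)) == 1L) {
    return(structure(list(statistic = u, df = NA_integer_, p_value = 1,
                          method = "mann_whitney_u",
                          notes = "all pooled values identical; test degenerate"),
                     class = "test_result"))
  }
  mu <- n1 * n2 / 2
  if (min(n1, n2) <= 8L) {
    # exact: U depends on the pooled ranks only through which positions go
    # to group 1, so enumerate all C(n1+n2, n1) assignments
    combos <- combn(n1 + n2, n1)
    us <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    notes <- "exact enumeration"
  } else {
    nn <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term)
    z <- (u - mu) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    notes <- "tie-corrected normal approximation"
  }
  structure(list(statistic = u, df = NA_integer_, p_value = p,
                 method = "mann_whitney_u", notes = notes),
            class = "test_result")
}

#' Build the 2x2 minute table from a window summary
#'
#' Rows are inside/outside the window; columns hypoglycemic /
#' not-hypoglycemic minutes: `(a, b, c, d) = (inside_hypo,
#' inside_monitored - inside_hypo, outside_hypo,
#' outside_monitored - outside_hypo)`.
#'
#' @param summary a `window_summary`.
#' @return 2x2 integer matrix with dimnames.
#' @export
build_minutes_table <- function(summary) {
  stopifnot(inherits(summary, "window_summary"))
  b <- summary$inside_monitored - summary$inside_hypo
  d <- summary$outside_monitored - summary$outside_hypo
  if (b < 0 || d < 0) stop("inconsistent summary: hypo minutes exceed monitored minutes")
  matrix(c(summary$inside_hypo, b, summary$outside_hypo, d),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("inside", "outside"), c("hypo", "not_hypo")))
}

# tendency label from the windowed risk ratio and hypo-minute share; a
# documented package convention, not a clinical scale
tendency_label <- function(risk_ratio, share, expected) {
  if (is.na(risk_ratio)) return("undefined")
  if (risk_ratio < 1.2 && abs(share - expected) <= 5) return("evenly distributed")
  if (risk_ratio >= 3) return("++")
  if (risk_ratio >= 2) return("+")
  if (risk_ratio >= 1.5) return("-")
  if (risk_ratio >= 1) return("--")
  "below average"
}

# derive the grouping factor for compare_subgroups
subgroup_labels <- function(metadata, grouping) {
  switch(grouping,
    age = ifelse(metadata$age_months >= 10, "age >= 10 months", "age < 10 months"),
    mutation = ifelse(metadata$mutation == "negative", "mutation-negative",
               ifelse(metadata$mutation == "not-done", NA_character_,
                      "mutation-positive")),
    medication = ifelse(vapply(metadata$medication, nzchar, logical(1)),
                        "on medication", "off medication"),
    diagnosis = metadata$diagnosis,
    stop("unknown grouping '", grouping,
         "' (use age, mutation, medication or diagnosis)"))
}

#' Compare subgroups within a clock window
#'
#' Splits the cohort by a metadata grouping (`"age"`: at 10 months,
#' `"mutation"`: positive vs negative with not-done excluded,
#' `"medication"`: on vs off, `"diagnosis"`: HI vs IKH), computes each
#' group's window summary, the Pearson chi-square on its inside/outside
#' minute table, and a qualitative tendency label from risk-ratio bands
#' (>= 3 "++", 2-3 "+", 1.5-2 "-", 1-1.5 "--"; "evenly distributed" when
#' the risk ratio is below 1.2 and the hypo-minute share is within 5
#' points of the expected share).
#'
#' @param traces list of [glucose_trace()] objects.
#' @param events pooled event data frame.
#' @param metadata data frame as from [read_metadata()].
#' @param grouping one of `"age"`, `"mutation"`, `"medication"`,
#'   `"diagnosis"`.
#' @param window a [clock_window()].
#' @param config a [detection_config()].
#' @return a `subgroup_comparison` list with per-group `n_patients`,
#'   `summary`, `test` and `tendency`.
#' @export
compare_subgroups <- function(traces, events, metadata, grouping, window,
                              config = detection_config()) {
  ids <- vapply(traces, function(tr) tr$patient_id, character(1))
  stopifnot(all(ids %in% metadata$patient_id))
  labels <- subgroup_labels(metadata, grouping)
  names(labels) <- metadata$patient_id
  groups <- list()
  for (g in sort(unique(stats::na.omit(labels)))) {
    members <- names(labels)[!is.na(labels) & labels == g]
    g_traces <- traces[ids %in% members]
    if (length(g_traces) == 0L || sum(vapply(g_traces, monitored_minutes,
                                             numeric(1))) == 0) {
      groups[[g]] <- list(n_patients = length(g_traces), summary = NULL,
                          test = NULL, tendency = "no data")
      next
    }
    g_events <- events[events$patient_id %in% members, , drop = FALSE]
    profile <- minutes_by_hour(g_traces, g_events, config)
    ws <- window_summary(profile, window)
    test <- tryCatch(pearson_chi2_2x2(build_minutes_table(ws)),
                     error = function(e) NULL)
    groups[[g]] <- list(
      n_patients = length(g_traces), summary = ws, test = test,
      tendency = tendency_label(ws$risk_ratio, ws$hypo_share_inside,
                                ws$expected_share))
  }
  structure(list(grouping = grouping, window = window, groups = groups),
            class = "subgroup_comparison")
}

#' @export
print.subgroup_comparison <- function(x, ...) {
  cat(sprintf("<subgroup_comparison> by %s, window [%02d:00, %02d:00)\n",
              x$grouping, x$window$start_hour, x$window$end_hour %% 24))
  for (g in names(x$groups)) {
    grp <- x$groups[[g]]
    if (is.null(grp$summary)) {
      cat(sprintf("  %s (n=%d): no data\n", g, grp$n_patients))
      next
    }
    cat(sprintf("  %s (n=%d): inside %.2f%%, outside %.2f%%, share %.2f%% (exp %.1f%%) -> %s",
                g, grp$n_patients, grp$summary$inside_percent,
                grp$summary$outside_percent, grp$summary$hypo_share_inside,
                grp$summary$expected_share, grp$tendency))
    if (!is.null(grp$test)) {
      cat(sprintf("  [chi2 %.1f, p %.2g]", grp$test$statistic, grp$test$p_value))
    }
    cat("\n")
  }
  invisible(x)
}

#' Serialize a subgroup comparison to JSON
#'
#' Mirrors the layout of a published subgroup table: per group the inside
#' and outside totals, hypoglycemic minutes and percents, the share of hypo
#' minutes inside the window against the expected share, the tendency
#' label, and the test statistic and p-value.
#'
#' @param comparison a `subgroup_comparison`.
#' @param path output JSON path (optional).
#' @return the report list, invisibly if written to `path`.
#' @export
subgroup_report <- function(comparison, path = NULL) {
  stopifnot(inherits(comparison, "subgroup_comparison"))
  rep <- list(grouping = comparison$grouping,
              window = sprintf("%02d:00-%02d:00",
                               comparison$window$start_hour,
                               comparison$window$end_hour %% 24),
              groups = lapply(comparison$groups, function(grp) {
                if (is.null(grp$summary)) {
                  return(list(n_patients = grp$n_patients, tendency = grp$tendency))
                }
                s <- grp$summary
                list(n_patients = grp$n_patients,
                     inside_monitored = s$inside_monitored,
                     inside_hypo = s$inside_hypo,
                     inside_percent = round(s$inside_percent, 2),
                     outside_monitored = s$outside_monitored,
                     outside_hypo = s$outside_hypo,
                     outside_percent = round(s$outside_percent, 2),
                     hypo_share_inside = round(s$hypo_share_inside, 2),
                     expected_share = round(s$expected_share, 1),
                     risk_ratio = round(s$risk_ratio, 3),
                     tendency = grp$tendency,
                     chi2 = if (!is.null(grp$test)) grp$test$statistic else NULL,
                     p_value = if (!is.null(grp$test)) grp$test$p_value else NULL)
              }))
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(rep))
  }
  rep
}
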