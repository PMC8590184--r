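test_that("chi-square is zero for identical row proportions", {
  expect_equal(pearson_chi2_2x2(10, 10, 10, 10)$statistic, 0)
  expect_equal(pearson_chi2_2x2(10, 10, 10, 10)$p_value, 1)
  expect_equal(pearson_chi2_2x2(10, 90, 20, 180)$statistic, 0)
})

test_that("chi-square matches the closed form and an independent implementation", {
  # hand evaluation for (5,5,1,9): N(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))
  hand <- 20 * (5 * 9 - 5 * 1)^2 / (10 * 10 * 6 * 14)
  res <- pearson_chi2_2x2(5, 5, 1, 9)
  expect_equal(res$statistic, hand)
  # cross-check closed form against stats::chisq.test on random tables
  set.seed(51)
  for (i in 1:20) {
    m <- matrix(sample(1:500, 4), 2)
    ours <- pearson_chi2_2x2(m)
    ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, unname(ref$p.value))
    ours_c <- pearson_chi2_2x2(m, correction = TRUE)
    ref_c <- suppressWarnings(stats::chisq.test(m, correct = TRUE))
    expect_equal(ours_c$statistic, unname(ref_c$statistic))
  }
})

test_that("chi-square is invariant under transposition/swaps and scales with counts", {
  set.seed(52)
  for (i in 1:10) {
    cells <- sample(1:200, 4)
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    s0 <- pearson_chi2_2x2(a, b, c, d)$statistic
    expect_equal(pearson_chi2_2x2(a, c, b, d)$statistic, s0)  # transpose
    expect_equal(pearson_chi2_2x2(c, d, a, b)$statistic, s0)  # row swap
    expect_equal(pearson_chi2_2x2(b, a, d, c)$statistic, s0)  # column swap
    k <- sample(2:7, 1)
    expect_equal(pearson_chi2_2x2(k * a, k * b, k * c, k * d)$statistic, k * s0)
  }
})

test_that("chi-square refuses degenerate margins naming them", {
  expect_error(pearson_chi2_2x2(0, 0, 5, 5), "row")
  expect_error(pearson_chi2_2x2(0, 5, 0, 5), "column")
})

test_that("Mann-Whitney handles overlap, separation and degenerate samples", {
  res <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$statistic, 4.5)
  expect_equal(res$p_value, 1)
  expect_equal(mann_whitney_u(c(1, 2), c(10, 20))$statistic, 0)
  deg <- mann_whitney_u(c(2, 2), c(2, 2, 2))
  expect_equal(deg$p_value, 1)
  expect_match(deg$notes, "degenerate")
})

test_that("U agrees with brute-force pair counting and U_x + U_y = n1 n2", {
  set.seed(53)
  for (i in 1:20) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- sample(1:6, n1, replace = TRUE)  # ties likely
    y <- sample(1:6, n2, replace = TRUE)
    ux <- mann_whitney_u(x, y)$statistic
    expect_equal(ux, brute_force_u(x, y))
    expect_equal(ux + mann_whitney_u(y, x)$statistic, n1 * n2)
  }
})

test_that("U is invariant under strictly monotone transforms of the pooled data", {
  set.seed(54)
  x <- rnorm(12); y <- rnorm(15, 0.5)
  base <- mann_whitney_u(x, y)
  for (f in list(function(v) exp(v), function(v) v^3, function(v) 5 * v - 2)) {
    tf <- mann_whitney_u(f(x), f(y))
    expect_equal(tf$statistic, base$statistic)
    expect_equal(tf$p_value, base$p_value)
  }
})

test_that("normal-approximation p agrees with wilcox.test without ties", {
  set.seed(55)
  x <- rnorm(20); y <- rnorm(25, 0.4)
  ours <- mann_whitney_u(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  # wilcox.test's W counts x > y pairs, same as our U
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-10)
})

test_that("exact p agrees with wilcox.test's exact p for small tie-free samples", {
  set.seed(56)
  for (i in 1:5) {
    x <- rnorm(5); y <- rnorm(7)
    ours <- mann_whitney_u(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-10)
  }
})

test_that("the minute table is assembled from a window summary", {
  ws <- window_summary_from_counts(25875, 1665, 123490, 3585, clock_window(3, 7))
  m <- build_minutes_table(ws)
  expect_equal(unname(m), matrix(c(1665, 24210, 3585, 119905), 2, byrow = TRUE))
  # equal rates give statistic zero on the resulting table
  ws0 <- window_summary_from_counts(10, 5, 10, 5, clock_window(3, 7))
  expect_equal(pearson_chi2_2x2(build_minutes_table(ws0))$statistic, 0)
  # all-zero hypo column is refused by the test
  wsz <- window_summary_from_counts(10, 0, 10, 0, clock_window(3, 7))
  expect_error(pearson_chi2_2x2(build_minutes_table(wsz)), "column")
})

test_that("subgroup comparison partitions cohort minutes and labels tendencies", {
  cfg <- simulation_config(n_patients = 10, days_range = c(3, 3),
                           dropout_prob = 0, seed = 99)
  sim <- simulate_cohort(cfg)
  dc <- detection_config()
  ev <- do.call(rbind, lapply(sim$traces, detect_events, config = dc))
  w <- clock_window(3, 7, "early hours")
  for (grouping in c("age", "medication")) {
    cmp <- compare_subgroups(sim$traces, ev, sim$metadata, grouping, w, dc)
    sums <- Filter(Negate(is.null), lapply(cmp$groups, `[[`, "summary"))
    tot_mon <- sum(vapply(sums, function(s) s$inside_monitored + s$outside_monitored,
                          numeric(1)))
    expect_equal(tot_mon, sum(vapply(sim$traces, monitored_minutes, numeric(1))))
    tot_hypo <- sum(vapply(sums, function(s) s$inside_hypo + s$outside_hypo,
                           numeric(1)))
    expect_equal(tot_hypo, sum(ev$duration_min))
    expect_true(all(vapply(cmp$groups, function(g) is.character(g$tendency),
                           logical(1))))
  }
  expect_error(compare_subgroups(sim$traces, ev, sim$metadata, "shoe size", w, dc),
               "unknown grouping")
})

test_that("tendency bands follow the documented risk-ratio convention", {
  expect_equal(cgmtempo:::tendency_label(3.2, 40, 16.7), "++")
  expect_equal(cgmtempo:::tendency_label(2.4, 33, 16.7), "+")
  expect_equal(cgmtempo:::tendency_label(1.7, 29, 16.7), "-")
  expect_equal(cgmtempo:::tendency_label(1.3, 25, 16.7), "--")
  expect_equal(cgmtempo:::tendency_label(1.05, 18, 16.7), "evenly distributed")
  expect_equal(cgmtempo:::tendency_label(0.5, 8, 16.7), "below average")
})
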