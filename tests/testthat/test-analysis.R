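test_that("day expansion hand-traces a transfer with re-assessment", {
  coh <- make_transfer_cohort()
  days <- expand_to_days(coh)
  expect_equal(nrow(days), 3L)
  expect_equal(as.character(days$setting), c("medium", "low", "low"))
  # day 1 has two observations with totals 3 and 6: daily max 6 -> unstable
  expect_equal(days$news_total_daily_max, c(6L, 0L, 19L))
  expect_equal(as.character(days$news_band),
               c("unstable", "stable", "critical"))
  # dependence: admission total 16 (average), re-assessed 24 (high) at transfer
  expect_equal(days$micd_total_current, c(16L, 24L, 24L))
  expect_equal(as.character(days$micd_level), c("average", "high", "high"))
  expect_equal(as.character(days$icc_level), c("Medium", "High", "High"))
})

test_that("missing-vitals policy: strict errors, carry-forward fills", {
  coh <- make_transfer_cohort()
  coh$vitals <- coh$vitals[coh$vitals$observed_at != as.Date("2020-01-21"), ]
  expect_error(expand_to_days(coh),
               class = "carecomplexity_validation_error")
  expect_message(
    days <- expand_to_days(coh, missing_vitals = "carry_forward"),
    "carry-forward"
  )
  # day 2 inherits day 1's daily maximum (6)
  expect_equal(days$news_total_daily_max, c(6L, 6L, 19L))
  # but a missing first day cannot be filled
  coh2 <- make_transfer_cohort()
  coh2$vitals <- coh2$vitals[coh2$vitals$observed_at != as.Date("2020-01-20"), ]
  expect_error(expand_to_days(coh2, missing_vitals = "carry_forward"),
               class = "carecomplexity_validation_error")
})

test_that("patient-days are conserved between records and day rows", {
  cfg <- cohort_config(
    n_patients = c(internal_medicine = 25, neurology = 5, pneumology = 5)
  )
  coh <- generate_cohort(cfg, seed = 21)
  days <- expand_to_days(coh)
  los <- as.integer(coh$patients$discharge_date - coh$patients$admission_date)
  expect_equal(nrow(days), sum(los))
  per_patient <- table(days$patient_id)
  expect_equal(unname(as.integer(per_patient[coh$patients$patient_id])), los)
})

test_that("inclusion filters apply rules in order and count exclusions", {
  p <- dplyr::bind_rows(
    make_patient_row("A", admission = "2020-01-20", discharge = "2020-01-25"),
    make_patient_row("B", admission = "2020-01-21", discharge = "2020-01-26"),
    make_patient_row("C", admission = "2020-02-01", discharge = "2020-02-05"),
    make_patient_row("D", admission = "2020-01-22", discharge = "2020-01-23",
                     admission_type = "day_hospital"),
    make_patient_row("E", admission = "2020-01-22", discharge = "2020-01-27",
                     admission_source = "external_ward"),
    make_patient_row("F", admission = "2020-01-02", discharge = "2020-01-10")
  )
  coh <- simple_cohort(p)
  res <- apply_inclusion_filters(coh, "2020-01-15", "2020-02-15")
  expect_setequal(res$cohort$patients$patient_id, c("A", "B", "C"))
  expect_equal(res$exclusions[["day_hospital"]], 1L)
  expect_equal(res$exclusions[["external_transfer"]], 1L)
  expect_equal(res$exclusions[["outside_window"]], 1L) # F discharged before window
  expect_equal(res$exclusions[["outpatient"]], 0L)
  # filtered cohort drops the excluded patients' satellite rows too
  expect_setequal(unique(res$cohort$vitals$patient_id), c("A", "B", "C"))

  empty <- apply_inclusion_filters(
    care_cohort(p[0, ], coh$settings[0, ], coh$vitals[0, ],
                coh$assessments[0, ]),
    "2020-01-15", "2020-02-15"
  )
  expect_equal(nrow(empty$cohort$patients), 0L)
  expect_true(all(empty$exclusions == 0L))
})

test_that("crosstab counts, half-up row percentages, and margins are exact", {
  rows <- counts_to_rows(reference_counts("instability"), "band")
  ct <- crosstab(rows, "setting", "band")
  expect_equal(sum(ct$counts), nrow(rows))
  expect_equal(ct$row_percent["low", "critical"], 16.8) # 55 of 327
  expect_equal(unname(ct$row_percent["Total", ]),
               unname(round_half_up(100 * colSums(ct$counts) / sum(ct$counts), 1)))
  # single-cell table
  one <- data.frame(a = "x", b = "y")
  ct1 <- crosstab(one, "a", "b")
  expect_equal(unname(ct1$row_percent["x", "y"]), 100.0)
  expect_true(is.na(ct1$chi2_stat))
  expect_error(crosstab(one[0, ], "a", "b"),
               class = "carecomplexity_validation_error")
})

test_that("chi-square is Pearson without correction; proportional rows give 0", {
  df <- data.frame(
    g = rep(c("a", "b"), c(30, 30)),
    h = rep(rep(c("x", "y"), 2), c(10, 20, 20, 10))
  )
  ct <- crosstab(df, "g", "h")
  expect_equal(ct$chi2_stat, 20 / 3, tolerance = 1e-12) # hand-computed Pearson
  expect_equal(ct$chi2_dof, 1)

  prop <- data.frame(
    g = rep(c("a", "b"), c(30, 60)),
    h = c(rep(c("x", "y"), c(10, 20)), rep(c("x", "y"), c(20, 40)))
  )
  expect_equal(crosstab(prop, "g", "h")$chi2_stat, 0, tolerance = 1e-12)
})

test_that("zero-margin factor levels are retained with zero counts", {
  rows <- counts_to_rows(reference_counts("instability"), "band")
  rows <- rows[rows$setting != "sub_intensive", ]
  ct <- crosstab(rows, "setting", "band")
  expect_true("sub_intensive" %in% rownames(ct$counts))
  expect_equal(unname(ct$counts["sub_intensive", ]), c(0L, 0L, 0L))
  expect_false(anyNA(ct$chi2_stat))
})

test_that("consistency analysis equals a hand count on a 10-day toy set", {
  toy <- tibble::tibble(
    setting = factor(c("low", "low", "low", "medium", "medium", "medium",
                       "high", "high", "sub_intensive", "sub_intensive"),
                     levels = setting_labels()),
    icc_level = factor(c("Low", "High", "Low", "Medium", "Low", "Medium",
                         "High", "Medium", "High", "Low"),
                       levels = icc_labels(), ordered = TRUE)
  )
  res <- consistency_analysis(toy)
  # hand count: low 2/3, medium 2/3, high 1/2, sub-intensive 1/2, overall 6/10
  get <- function(s) res[res$setting == s, ]
  expect_equal(get("low")$n_consistent / get("low")$n_days, 2 / 3)
  expect_equal(get("medium")$n_consistent, 2L)
  expect_equal(get("high")$proportion, 0.5)
  expect_equal(get("sub_intensive")$proportion, 0.5)
  expect_equal(get("overall")$proportion, 0.6)
  expect_equal(get("overall")$n_days, 10L)

  # all High-complexity days sitting in low care: zero consistency there
  roof <- tibble::tibble(
    setting = factor(rep("low", 4), levels = setting_labels()),
    icc_level = factor(rep("High", 4), levels = icc_labels(), ordered = TRUE)
  )
  expect_equal(consistency_analysis(roof)$proportion[
    consistency_analysis(roof)$setting == "low"], 0)
})

test_that("per-patient summary tallies outcomes by admission complexity", {
  p <- dplyr::bind_rows(
    make_patient_row("A", admission = "2020-01-20", discharge = "2020-01-24",
                     outcome = "death", drg = 1000),
    make_patient_row("B", admission = "2020-01-20", discharge = "2020-01-22",
                     outcome = "death", drg = 2000),
    make_patient_row("C", admission = "2020-01-20", discharge = "2020-01-26",
                     outcome = "ordinary_discharge", drg = 3000),
    make_patient_row("D", admission = "2020-01-20", discharge = "2020-01-23",
                     outcome = "transfer_higher_care", drg = 4000),
    make_patient_row("E", admission = "2020-01-20", discharge = "2020-01-25",
                     outcome = "ordinary_discharge", drg = 5000),
    make_patient_row("F", admission = "2020-01-21", discharge = "2020-01-27",
                     outcome = "ordinary_discharge", drg = 6000)
  )
  coh <- simple_cohort(p)
  # A, B admitted critical (total 19); D unstable with high dependence
  worst <- function(id, d) make_vitals_row(id, d, rr = 26, spo2 = 90,
                                           o2 = TRUE, temp = 39.5, sbp = 85,
                                           hr = 135, avpu = "U")
  coh$vitals <- dplyr::bind_rows(
    worst("A", "2020-01-20"), worst("B", "2020-01-20"),
    coh$vitals[!coh$vitals$patient_id %in% c("A", "B"), ]
  )
  coh$assessments[coh$assessments$patient_id == "D", micd_dimension_names()] <- 4

  res <- per_patient_summary(coh)
  high <- res[res$admission_icc == "High", ]
  # A, B (critical) and D (stable + high dependence) are High at admission
  expect_equal(high$n, 3L)
  expect_equal(high$n_death, 2L)
  expect_equal(high$n_transfer_higher, 1L)
  expect_equal(high$mean_los_days, mean(c(4, 2, 3)))
  expect_equal(high$mean_drg_value, mean(c(1000, 2000, 4000)))
  med <- res[res$admission_icc == "Medium", ]
  expect_equal(med$n, 3L) # C, E, F: stable, dependence 16 -> average
  expect_equal(med$n_death, 0L)
  expect_equal(sum(res$n), 6L)

  # a single patient yields a one-row-per-class table with that patient only
  solo <- simple_cohort(p[3, ])
  res1 <- per_patient_summary(solo)
  expect_equal(sum(res1$n), 1L)
  expect_equal(res1$n[res1$admission_icc == "Medium"], 1L)

  # records without an admission assessment are flagged and excluded
  noadm <- simple_cohort(p)
  noadm$assessments <- noadm$assessments[noadm$assessments$patient_id != "F", ]
  res2 <- per_patient_summary(noadm)
  expect_equal(attr(res2, "flagged"), "F")
  expect_equal(sum(res2$n), 5L)
})

test_that("group comparison reproduces hand-computed rank statistics", {
  # identical groups: no rank separation, H = 0 (groups of 3 trip the
  # Shapiro-Wilk size guard, which is not under test here)
  same <- suppressWarnings(
    group_comparison(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  )
  expect_equal(same$kruskal_h, 0, tolerance = 1e-12)
  # fully separated groups: H = 12/(9*10) * 3*((2-5)^2+(5-5)^2+(8-5)^2) = 7.2
  sep <- suppressWarnings(
    group_comparison(1:9, rep(c("a", "b", "c"), each = 3))
  )
  expect_equal(sep$kruskal_h, 7.2, tolerance = 1e-12)
  expect_equal(sep$kruskal_dof, 2)
})

test_that("Shapiro-Wilk flags non-normal data and warns off-range n", {
  set.seed(31)
  res <- group_comparison(runif(900), rep(c("a", "b"), each = 450))
  expect_true(all(res$shapiro$p < 0.05)) # uniform data, n = 450 per group
  expect_warning(
    group_comparison(c(1, 2, 4, 1:10), rep(c("a", "b"), c(3, 10))),
    class = "carecomplexity_shapiro_n_warning"
  )
  expect_error(group_comparison(1:5, rep("a", 5)),
               class = "carecomplexity_validation_error")
})
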