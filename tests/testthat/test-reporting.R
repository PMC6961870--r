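test_that("scenario summaries recount outcomes with nearest-integer percentages", {
  set <- walk_setup()
  co <- walk_query(601)
  outcomes <- suppressWarnings(run_scenarios(co, set$models))
  summ <- summarize_scenarios(outcomes, co)

  expect_equal(nrow(summ), 4)
  for (s in c("A", "B", "C", "D")) {
    oc <- outcomes[outcomes$scenario == s, ]
    row <- summ[summ$scenario == s, ]
    expect_equal(row$n_tested, sum(oc$csf_tested))
    expect_equal(row$n_diagnosed, sum(oc$diagnosed))
    expect_equal(row$pct_tested,
                 round_half_away(100 * sum(oc$csf_tested) / nrow(oc)))
    expect_equal(row$pct_diagnosed,
                 round_half_away(100 * sum(oc$diagnosed) / nrow(oc)))
  }
  expect_equal(summ$pct_tested[summ$scenario == "B"], 0)
  expect_equal(summ$pct_tested[summ$scenario == "D"], 100)

  # mismatched cohorts are refused
  broken <- outcomes[-1, ]
  expect_error(summarize_scenarios(broken, co), "mismatched")
})

test_that("half-away-from-zero rounding matches the printed convention", {
  expect_equal(round_half_away(c(0.5, 1.5, 2.5, -0.5, -2.5)),
               c(1, 2, 3, -1, -3))
  expect_equal(round_half_away(100 * 140 / 535), 26)
  expect_equal(round_half_away(100 * 379 / 535), 71)
})

test_that("two-sample proportion test reproduces the published differences", {
  ab <- two_sample_proportion_test(379, 535, 308, 535)
  expect_equal(round_half_away(ab$diff), 13)
  expect_lt(ab$p, 0.001)
  expect_true(ab$ci_low <= ab$diff && ab$diff <= ab$ci_high)

  ac <- two_sample_proportion_test(140, 535, 295, 535)
  expect_equal(round_half_away(ac$diff), -29)
  expect_lt(ac$p, 0.001)

  ad <- two_sample_proportion_test(379, 535, 348, 535)
  expect_equal(round_half_away(ad$diff), 6)
})

test_that("proportion z is antisymmetric, matches chi-square, and handles the null", {
  a <- two_sample_proportion_test(140, 535, 295, 535)
  b <- two_sample_proportion_test(295, 535, 140, 535)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)

  # pooled z^2 equals the uncorrected chi-square statistic
  pt <- prop.test(c(140, 295), c(535, 535), correct = FALSE)
  expect_equal(a$z^2, unname(pt$statistic), tolerance = 1e-12)

  eq <- two_sample_proportion_test(50, 100, 100, 200)
  expect_equal(eq$diff, 0)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)

  degenerate <- two_sample_proportion_test(0, 10, 0, 10)
  expect_equal(degenerate$z, 0)
  expect_equal(degenerate$p, 1)
})

mk_outcomes <- function(groups, ids) {
  tibble::tibble(
    patient_id = ids, scenario = "A",
    csf_tested = groups %in% 3:4, pcc_step1 = 0.5,
    pcc_sim_positive = NA_real_, pcc_sim_negative = NA_real_,
    trigger = NA_character_, pcc_final = 0.5, predicted = "AD",
    diagnosed = groups %in% c(1, 3), decision_group = groups,
    margin_nocsf = 0.1, dsi_ad_nocsf = 0.5, csf_incomplete = FALSE
  )
}

test_that("decision-group ANOVA matches the closed-form F on a nine-value fixture", {
  ids <- sprintf("P%02d", 1:9)
  co <- as_cohort(tibble::tibble(
    patient_id = ids,
    age = c(1, 2, 3, 4, 5, 6, 7, 8, 9) + 40,  # groups {41,42,43},{44,45,46},{47,48,49}
    sex = "F", diagnosis = rep(c("CONTROL", "AD", "FTD"), 3),
    mmse = rep(20, 9)
  ))
  oc <- mk_outcomes(rep(1:3, each = 3), ids)
  tab <- group_characteristics(co, oc)
  age_rows <- tab[tab$variable == "age", ]
  # group means 42, 45, 48; SSB = 54, SSW = 6, df = (2, 6) -> F = 27
  expect_equal(age_rows$statistic[1], 27, tolerance = 1e-9)
  expect_equal(age_rows$p_value[1], pf(27, 2, 6, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_equal(age_rows$mean[1:3], c(42, 45, 48))
  expect_true(is.na(age_rows$mean[4]))
  expect_true("Difference with second DSI without CSF" %in% tab$label)
})

test_that("equal-mean groups give a null ANOVA", {
  ids <- sprintf("P%02d", 1:9)
  co <- as_cohort(tibble::tibble(
    patient_id = ids,
    age = rep(c(50, 60, 70), 3),
    sex = "F", diagnosis = rep(c("CONTROL", "AD", "FTD"), 3),
    mmse = 20
  ))
  oc <- mk_outcomes(rep(1:3, each = 3), ids)
  tab <- group_characteristics(co, oc)
  age_rows <- tab[tab$variable == "age", ]
  expect_lt(abs(age_rows$statistic[1]), 1e-9)
  expect_equal(age_rows$p_value[1], 1, tolerance = 1e-9)
})

test_that("patient reports are deterministic and recommend per the simulated PCCs", {
  set <- walk_setup()
  co <- walk_cohort()
  outcomes <- suppressWarnings(run_scenarios(co, set$models, scenarios = "A"))

  g1 <- outcomes$patient_id[outcomes$decision_group == 1][1]
  r1 <- patient_report(co, set$models, g1)
  expect_identical(r1, patient_report(co, set$models, g1))
  expect_match(r1, "Directly diagnosed without CSF")
  expect_no_match(r1, "Simulated|simulated CSF biomarker profiles")

  g3 <- outcomes$patient_id[outcomes$decision_group == 3][1]
  r3 <- patient_report(co, set$models, g3)
  expect_match(r3, "CSF measurement is considered potentially useful")
  expect_match(r3, "actual CSF biomarker values")

  g2 <- outcomes$patient_id[outcomes$decision_group == 2][1]
  r2 <- patient_report(co, set$models, g2)
  expect_match(r2, "CSF measurement is not considered useful")
  expect_no_match(r2, "actual CSF biomarker values")

  expect_error(patient_report(co, set$models, "NOBODY"), "not found")
})
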