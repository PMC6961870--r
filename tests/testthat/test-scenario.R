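test_that("simulated CSF profiles are per-group medians of corrected values", {
  df <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:10),
    age = 65, sex = "F",
    diagnosis = rep(c("AD", "CONTROL"), each = 5),
    ab42 = c(rep(535, 5), c(500, 520, 540, 560, 580)),
    total_tau = c(701, 699, 693, 640, 710, rep(300, 5)),
    p_tau = c(80:84, 50:54)
  )
  co <- as_cohort(df, corrected = TRUE)
  prof <- simulated_csf_profiles(co)

  pos <- prof[prof$polarity == "positive", ]
  neg <- prof[prof$polarity == "negative", ]
  expect_equal(pos$ab42, 535)            # degenerate: all AD values equal
  expect_equal(neg$ab42, 540)            # sort-and-pick middle of 5
  # positive always from AD, negative always from controls, never mixed
  sortpick <- function(x) sort(x)[(length(x) + 1) / 2]
  expect_equal(pos$total_tau, sortpick(df$total_tau[df$diagnosis == "AD"]))
  expect_equal(neg$total_tau, sortpick(df$total_tau[df$diagnosis == "CONTROL"]))
  expect_equal(pos$p_tau, 82)
  expect_equal(neg$p_tau, 52)

  too_few <- as_cohort(df[c(1:2, 6:10), ], corrected = TRUE)
  expect_error(simulated_csf_profiles(too_few), "AD")
})

test_that("the twelve-patient walk matches a straight-line reimplementation of the flow chart", {
  set <- walk_setup()
  co <- walk_cohort()
  outcomes <- suppressWarnings(
    run_scenarios(co, set$models, scenarios = "A")
  )
  expect_setequal(unique(outcomes$decision_group), 1:4)

  for (i in seq_len(nrow(co))) {
    oracle <- oracle_scenario_a(co[i, ], set$models)
    row <- outcomes[outcomes$patient_id == co$patient_id[i], ]
    msg <- paste("patient", co$patient_id[i])
    expect_equal(row$decision_group, oracle$decision_group, info = msg)
    expect_equal(row$csf_tested, oracle$csf_tested, info = msg)
    expect_equal(row$diagnosed, oracle$diagnosed, info = msg)
    expect_equal(row$trigger, oracle$trigger, info = msg)
    expect_equal(row$pcc_final, oracle$pcc_final, info = msg)
    expect_equal(row$predicted, oracle$predicted, info = msg)
  }
})

test_that("scenario A steps exit where the flow chart says they do", {
  set <- walk_setup()
  co <- walk_cohort()
  outcomes <- suppressWarnings(run_scenarios(co, set$models, scenarios = "A"))

  step1 <- outcomes[outcomes$pcc_step1 >= 0.8, ]
  expect_true(all(step1$decision_group == 1))
  expect_true(all(!step1$csf_tested))
  expect_true(all(is.na(step1$trigger)))
  expect_true(all(step1$diagnosed))

  g2 <- outcomes[outcomes$decision_group == 2, ]
  expect_true(all(g2$trigger == "none"))
  expect_true(all(!g2$csf_tested))
  expect_true(all(g2$pcc_sim_positive < 0.8 & g2$pcc_sim_negative < 0.8))

  tested <- outcomes[outcomes$csf_tested, ]
  expect_true(all(tested$trigger %in%
                    c("positive_only", "negative_only", "both")))
  expect_true(all(tested$decision_group %in% 3:4))

  # decision groups partition the cohort
  expect_setequal(unique(outcomes$decision_group), 1:4)
  expect_equal(sum(outcomes$decision_group %in% 1:4), nrow(co))
  expect_setequal(outcomes$patient_id[outcomes$decision_group %in% c(1, 3)],
                  outcomes$patient_id[outcomes$diagnosed])
})

test_that("scenarios B, C and D test exactly whom they should", {
  set <- walk_setup()
  co <- walk_query(411)
  ev <- suppressWarnings(triage_evaluate(co, set$models))
  outcomes <- run_scenarios(ev)

  b <- outcomes[outcomes$scenario == "B", ]
  d <- outcomes[outcomes$scenario == "D", ]
  c_ <- outcomes[outcomes$scenario == "C", ]
  expect_true(all(!b$csf_tested))
  expect_true(all(d$csf_tested))
  expect_setequal(c_$patient_id[c_$csf_tested],
                  ev$patient_id[ev$dsi_ad_nocsf > 0.6])

  # nesting: everyone diagnosed without CSF is directly diagnosed (group
  # 1) under the stepwise policy
  a <- outcomes[outcomes$scenario == "A", ]
  expect_true(all(a$decision_group[match(b$patient_id[b$diagnosed],
                                         a$patient_id)] == 1))
  expect_gte(sum(a$diagnosed), sum(b$diagnosed))

  # determinism
  expect_identical(outcomes, run_scenarios(ev))
})

test_that("a tested patient without actual CSF values is a hard error", {
  set <- walk_setup()
  co <- walk_cohort()
  tested_id <- suppressWarnings(
    run_scenarios(co, set$models, scenarios = "A")
  )
  tested_id <- tested_id$patient_id[tested_id$csf_tested][1]
  co$ab42[co$patient_id == tested_id] <- NA
  expect_error(
    suppressWarnings(run_scenarios(co, set$models, scenarios = "A")),
    tested_id
  )
  expect_error(
    suppressWarnings(run_scenarios(co, set$models, scenarios = "A")),
    "ab42"
  )
  # scenario D carries the patient, flagged
  d <- suppressWarnings(run_scenarios(co, set$models, scenarios = "D"))
  expect_true(d$csf_incomplete[d$patient_id == tested_id])
})

test_that("share diagnosed falls weakly with the PCC cutoff, for every scenario", {
  set <- walk_setup()
  for (seed in 501:505) {
    ev <- suppressWarnings(triage_evaluate(walk_query(seed), set$models))
    sweep <- sweep_pcc_cutoffs(ev, cutoffs = seq(0.5, 0.95, by = 0.05))
    for (s in c("A", "B", "C", "D")) {
      sh <- sweep$share_diagnosed[sweep$scenario == s]
      expect_true(all(diff(sh) <= 1e-12), info = paste("seed", seed, s))
    }
    # stepwise diagnoses at least as many as no-CSF at every cutoff
    a <- sweep$share_diagnosed[sweep$scenario == "A"]
    b <- sweep$share_diagnosed[sweep$scenario == "B"]
    expect_true(all(a >= b - 1e-12), info = paste("seed", seed))
    expect_true(all(sweep$share_tested[sweep$scenario == "B"] == 0))
    expect_true(all(sweep$share_tested[sweep$scenario == "D"] == 1))
  }
})
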