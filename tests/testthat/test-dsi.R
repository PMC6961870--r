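test_that("fitness function matches the counting definition on the worked example", {
  ff <- fit_fitness_function(c(1, 3, 5), c(0, 2, 4))
  expect_equal(evaluate_fitness(ff, 2.5), 0.5)       # FN = FP = 1/3
  expect_equal(evaluate_fitness(ff, -10), 0)         # below pooled minimum
  expect_equal(evaluate_fitness(ff, 10), 1)          # above pooled maximum
  expect_equal(ff$relevance, 1 / 3)
  expect_equal(ff$orientation, 1L)
})

test_that("fitness is linearly interpolated across a separation gap", {
  ff <- fit_fitness_function(c(10, 11), c(0, 1))
  expect_equal(evaluate_fitness(ff, 5.5), 0.5)       # midpoint of (1, 10)
  expect_equal(evaluate_fitness(ff, 1 + 0.25 * 9), 0.25)
  expect_equal(ff$relevance, 1)                      # perfectly separated
})

test_that("degenerate references give a constant neutral fitness with a warning", {
  expect_warning(ff <- fit_fitness_function(c(2, 2, 2), c(2, 2)),
                 "degenerate")
  expect_true(ff$degenerate)
  expect_equal(evaluate_fitness(ff, c(0, 2, 7)), c(0.5, 0.5, 0.5))
  expect_equal(ff$relevance, 0)
  expect_error(fit_fitness_function(numeric(0), c(1, 2)), "at least one")
})

test_that("relevance equals the exhaustive Youden scan", {
  expect_equal(compute_relevance(c(1, 3, 5), c(0, 2, 4)), 1 / 3)
  expect_equal(compute_relevance(c(2, 3), c(0, 1)), 1)
  expect_equal(compute_relevance(c(1, 2, 3), c(1, 2, 3)), 0)

  for (seed in 1:20) {
    vals <- withr::with_seed(seed, list(
      pos = round(rnorm(sample(3:12, 1), 1, 2), 1),
      neg = round(rnorm(sample(3:12, 1), 0, 2), 1)
    ))
    expect_equal(compute_relevance(vals$pos, vals$neg),
                 oracle_relevance(vals$pos, vals$neg),
                 tolerance = 1e-12, info = paste("seed", seed))
  }
})

test_that("fitness values match the brute-force oracle on random small references", {
  for (seed in 1:20) {
    vals <- withr::with_seed(seed, list(
      pos = round(rnorm(sample(3:10, 1), 1, 2), 1),
      neg = round(rnorm(sample(3:10, 1), 0, 2), 1),
      q = round(rnorm(15, 0.5, 3), 2)
    ))
    ff <- suppressWarnings(fit_fitness_function(vals$pos, vals$neg))
    expect_equal(evaluate_fitness(ff, vals$q),
                 oracle_fitness(vals$pos, vals$neg, vals$q),
                 tolerance = 1e-12, info = paste("seed", seed))
  }
})

test_that("fitness is weakly monotone along its orientation and bounded", {
  for (seed in 1:10) {
    vals <- withr::with_seed(seed, list(
      pos = rnorm(8, sample(c(-2, 2), 1), 2), neg = rnorm(8, 0, 2)
    ))
    ff <- suppressWarnings(fit_fitness_function(vals$pos, vals$neg))
    grid <- seq(min(c(vals$pos, vals$neg)) - 1,
                max(c(vals$pos, vals$neg)) + 1, length.out = 200)
    f <- evaluate_fitness(ff, grid)
    expect_true(all(f >= 0 & f <= 1))
    d <- diff(f) * ff$orientation
    expect_true(all(d >= -1e-12))
  }
})

test_that("pairwise DSI is the relevance-weighted mean of fitness values", {
  # two features with weights 0.5 and 0.25 and fitness 1.0 and 0.0:
  # (0.5 * 1 + 0.25 * 0) / 0.75 = 2/3
  ff1 <- structure(list(pos = c(1, 2), neg = c(0, 0.5), orientation = 1L,
                        relevance = 0.5, degenerate = FALSE),
                   class = "fitness_function")
  ff2 <- structure(list(pos = c(1, 2), neg = c(0, 0.5), orientation = 1L,
                        relevance = 0.25, degenerate = FALSE),
                   class = "fitness_function")
  res <- csftriage:::pair_dsi_values(list(a = ff1, b = ff2),
                                     list(a = 100, b = -100))
  expect_equal(res$dsi, 2 / 3)
  expect_equal(res$n, 2L)

  # single feature: pairwise DSI equals that feature's fitness value
  res1 <- csftriage:::pair_dsi_values(list(a = ff1), list(a = 100, b = NA))
  expect_equal(res1$dsi, 1)

  # nothing observed: undefined, not silently zero
  res0 <- csftriage:::pair_dsi_values(list(a = ff1), list(a = NA, b = NA))
  expect_true(is.na(res0$dsi))
  expect_equal(res0$n, 0L)
})

test_that("total DSI averages the three pairwise comparisons per group", {
  # build a model whose six single-feature pairs produce fixed fitness
  # values at the record's feature values: pos = neg = 1:10 makes
  # f(x) = share(ref < x) / 1, so x = 9.5 gives 0.9 etc.
  mk <- function(val_for_f) {
    structure(list(pos = as.double(1:10), neg = as.double(1:10),
                   orientation = 1L, relevance = 1, degenerate = FALSE),
              class = "fitness_function")
  }
  pairs <- c("CONTROL_vs_AD", "CONTROL_vs_FTD", "CONTROL_vs_VAD",
             "AD_vs_FTD", "AD_vs_VAD", "VAD_vs_FTD")
  feats <- c("mmse", "tmt_a", "tmt_b", "ravlt_recall", "cgca", "wmh_ml")
  model <- structure(
    list(pairs = setNames(lapply(seq_along(pairs), function(i) {
      setNames(list(mk()), feats[i])
    }), pairs), features = feats, min_ref = 5,
    group_sizes = c(CONTROL = 10, AD = 10, FTD = 10, VAD = 10)),
    class = "dsi_model"
  )
  # stored pairwise values: CONTROL_vs_AD = 0.1, AD_vs_FTD = 0.6,
  # AD_vs_VAD = 0.6  ->  totals[AD] = mean(0.9, 0.6, 0.6) = 0.7
  values <- list(mmse = 1.5, tmt_a = 5.5, tmt_b = 5.5,
                 ravlt_recall = 6.5, cgca = 6.5, wmh_ml = 5.5)
  ev <- csftriage:::dsi_eval_record(model, values)
  expect_equal(unname(ev$totals["AD"]), 0.7)
  expect_equal(unname(ev$pairwise["CONTROL_vs_AD"]), 0.1)

  # complement symmetry: group totals recomputed from stored pairwise
  # values and their complements agree with the engine
  expect_equal(unname(ev$totals["CONTROL"]),
               mean(c(0.1, ev$pairwise[["CONTROL_vs_FTD"]],
                      ev$pairwise[["CONTROL_vs_VAD"]])))
})

test_that("an all-neutral profile ties and falls back to the fixed group order", {
  df <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:24),
    age = 60, sex = rep(c("F", "M"), 12),
    diagnosis = rep(c("CONTROL", "AD", "FTD", "VAD"), each = 6),
    mmse = 25, tmt_a = 50  # constant across groups: degenerate everywhere
  )
  co <- as_cohort(df, corrected = TRUE)
  model <- fit_dsi(co, c("mmse", "tmt_a"))
  cls <- dsi_classify(co[1, ], model)
  expect_equal(cls$dsi_CONTROL, 0.5)
  expect_equal(cls$dsi_VAD, 0.5)
  expect_true(cls$tie)
  expect_equal(cls$predicted, "CONTROL")
  expect_equal(cls$margin, 0)
})

test_that("DSI values equal a brute-force recomputation on small references", {
  for (seed in c(1, 2, 3)) {
    ref <- oracle_test_cohort(8, seed, miss_rate = 0.15)
    feats <- c("mmse", "tmt_a", "ab42")
    model <- fit_dsi(ref, feats)
    for (i in c(1, 9, 17, 25, 31)) {
      values <- as.list(ref[i, feats])
      ev <- csftriage:::dsi_eval_record(model, values)
      oracle <- oracle_totals(ref, values, feats)
      expect_equal(unname(ev$totals), unname(oracle), tolerance = 1e-9,
                   info = paste("seed", seed, "record", i))
      expect_equal(ev$predicted,
                   names(oracle)[which.max(oracle)],
                   info = paste("seed", seed, "record", i))
    }
  }
})

test_that("missing a feature is the same as excluding it from the subset", {
  ref <- oracle_test_cohort(8, 5)
  full <- fit_dsi(ref, c("mmse", "tmt_a", "ab42"))
  reduced <- fit_dsi(ref, c("mmse", "ab42"))
  values <- list(mmse = 24, tmt_a = NA_real_, ab42 = 600)
  ev_full <- csftriage:::dsi_eval_record(full, values)
  ev_red <- csftriage:::dsi_eval_record(reduced, values[c("mmse", "ab42")])
  expect_equal(ev_full$totals, ev_red$totals, tolerance = 1e-12)
})

test_that("model fitting is deterministic and enforces group presence", {
  ref <- oracle_test_cohort(8, 9)
  m1 <- fit_dsi(ref, c("mmse", "tmt_a"))
  m2 <- fit_dsi(ref, c("mmse", "tmt_a"))
  expect_identical(m1, m2)

  no_vad <- as_cohort(ref[ref$diagnosis != "VAD", ], corrected = TRUE)
  expect_error(fit_dsi(no_vad, c("mmse", "tmt_a")), "VAD")
})

test_that("features below min_ref are absent for that pair only", {
  ref <- oracle_test_cohort(8, 3)
  ref$ab42[ref$diagnosis == "VAD"][1:5] <- NA  # 3 left < min_ref
  ref <- as_cohort(ref, corrected = TRUE)
  model <- fit_dsi(ref, c("mmse", "ab42"))
  expect_false("ab42" %in% names(model$pairs$AD_vs_VAD))
  expect_true("ab42" %in% names(model$pairs$CONTROL_vs_AD))
})

test_that("bounded totals and margins on a generated cohort", {
  cfg <- default_generator_config()
  cfg$group_sizes <- c(CONTROL = 20L, AD = 30L, FTD = 12L, VAD = 8L)
  cfg$seed <- 31L
  cc <- correct_cohort(generate_cohort(cfg))$cohort
  model <- fit_dsi(cc, feature_subset("csf"))
  cls <- dsi_classify(cc, model)
  tot <- as.matrix(cls[, c("dsi_CONTROL", "dsi_AD", "dsi_FTD", "dsi_VAD")])
  expect_true(all(tot >= 0 & tot <= 1))
  expect_true(all(cls$margin >= 0))
  expect_true(all(cls$d2 <= cls$d1))
})

test_that("wider group separation never shrinks the median margin", {
  meds <- sapply(1:5, function(seed) {
    sapply(c(0.5, 1, 2), function(s) {
      cfg <- default_generator_config()
      cfg$group_sizes <- c(CONTROL = 24L, AD = 48L, FTD = 14L, VAD = 7L)
      cfg$separation_scale <- s
      cfg$seed <- 100L + seed
      cc <- correct_cohort(generate_cohort(cfg))$cohort
      model <- fit_dsi(cc, feature_subset("csf"))
      median(dsi_classify(cc, model)$margin)
    })
  })
  expect_true(all(diff(apply(meds, 1, median)) >= 0))
  expect_true(all(meds[1, ] <= meds[3, ]))
})

test_that("DSI models survive a JSON round trip", {
  ref <- oracle_test_cohort(8, 13)
  model <- fit_dsi(ref, c("mmse", "tmt_a", "ab42"))
  path <- withr::local_tempfile(fileext = ".json")
  write_dsi_model(model, path)
  back <- read_dsi_model(path)
  values <- list(mmse = 23.5, tmt_a = 77, ab42 = 520)
  expect_equal(csftriage:::dsi_eval_record(back, values)$totals,
               csftriage:::dsi_eval_record(model, values)$totals,
               tolerance = 1e-12)
  expect_equal(tidy(back)$relevance, tidy(model)$relevance)
})
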