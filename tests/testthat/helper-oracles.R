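# Independent brute-force reimplementations used as oracles.  These
# deliberately use plain loops and exhaustive scans, and share no code
# with the package internals they check.

# Exhaustive Youden scan over midpoints between sorted distinct pooled
# values plus +/- infinity, for both orientations.  Returns list
# (relevance, orientation): orientation +1 means high values indicate
# the positive group, ties broken toward +1.
oracle_orientation <- function(pos, neg) {
  pos <- pos[!is.na(pos)]
  neg <- neg[!is.na(neg)]
  v <- sort(unique(c(pos, neg)))
  mids <- c(-Inf, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2, Inf)
  j_hi <- -Inf
  j_lo <- -Inf
  for (c0 in mids) {
    sens_hi <- sum(pos >= c0) / length(pos)
    spec_hi <- sum(neg < c0) / length(neg)
    j_hi <- max(j_hi, sens_hi + spec_hi - 1)
    sens_lo <- sum(pos <= c0) / length(pos)
    spec_lo <- sum(neg > c0) / length(neg)
    j_lo <- max(j_lo, sens_lo + spec_lo - 1)
  }
  if (j_hi >= j_lo) list(relevance = j_hi, orientation = 1) else
    list(relevance = j_lo, orientation = -1)
}

oracle_relevance <- function(pos, neg) oracle_orientation(pos, neg)$relevance

# Direct-counting fitness: f(x) = FN/(FN+FP) with FN the share of
# positive reference values on the negative side of the cutoff x and FP
# the share of negative values on the positive side; linear
# interpolation across an FN + FP = 0 separation gap.
oracle_fitness <- function(pos, neg, x) {
  pos <- pos[!is.na(pos)]
  neg <- neg[!is.na(neg)]
  if (length(unique(c(pos, neg))) == 1) return(rep(0.5, length(x)))
  orient <- oracle_orientation(pos, neg)$orientation
  if (orient < 0) {
    pos <- -pos
    neg <- -neg
    x <- -x
  }
  sapply(x, function(x0) {
    fn <- sum(pos < x0) / length(pos)
    fp <- sum(neg >= x0) / length(neg)
    if (fn + fp > 0) return(fn / (fn + fp))
    a <- max(neg)
    b <- min(pos)
    (x0 - a) / (b - a)
  })
}

oracle_pair_names <- function() {
  list(c("CONTROL", "AD"), c("CONTROL", "FTD"), c("CONTROL", "VAD"),
       c("AD", "FTD"), c("AD", "VAD"), c("VAD", "FTD"))
}

# Pairwise DSI for one record by direct counting: relevance-weighted
# mean of fitness values over observed features with >= min_ref
# reference observations in both groups; zero-relevance features are
# skipped; all-zero weights give the neutral 0.5; no usable feature
# gives NA.
oracle_pairwise <- function(reference, values, positive, negative,
                            features, min_ref = 5) {
  num <- 0; den <- 0; n_used <- 0
  for (f in features) {
    x <- values[[f]]
    if (is.null(x) || is.na(x)) next
    pos <- reference[[f]][reference$diagnosis == positive]
    neg <- reference[[f]][reference$diagnosis == negative]
    pos <- pos[!is.na(pos)]
    neg <- neg[!is.na(neg)]
    if (length(pos) < min_ref || length(neg) < min_ref) next
    n_used <- n_used + 1
    w <- oracle_relevance(pos, neg)
    if (w <= 0) next
    num <- num + w * oracle_fitness(pos, neg, x)
    den <- den + w
  }
  if (n_used == 0) return(NA_real_)
  if (den == 0) return(0.5)
  num / den
}

# Total DSI per group: mean over the three pairwise comparisons with
# the group on the positive side, reversed canonical pairs entering as
# the complement 1 - value.
oracle_totals <- function(reference, values, features, min_ref = 5) {
  groups <- c("CONTROL", "AD", "FTD", "VAD")
  pw <- lapply(oracle_pair_names(), function(p) {
    oracle_pairwise(reference, values, p[1], p[2], features, min_ref)
  })
  totals <- sapply(groups, function(g) {
    vals <- c()
    for (i in seq_along(pw)) {
      p <- oracle_pair_names()[[i]]
      if (is.na(pw[[i]])) next
      if (p[1] == g) vals <- c(vals, pw[[i]])
      if (p[2] == g) vals <- c(vals, 1 - pw[[i]])
    }
    mean(vals)
  })
  totals
}

# Straight-line reimplementation of the four-scenario flow chart for a
# single patient, working directly from classifier calls; independent
# of the package's scenario engine.
oracle_scenario_a <- function(record_corrected, models, thr = 0.80) {
  cls0 <- suppressWarnings(dsi_classify(record_corrected, models$dsi_nocsf))
  pcc1 <- estimate_pcc(models$pcc_nocsf, cls0$d1, cls0$margin)$value
  if (pcc1 >= thr) {
    return(list(csf_tested = FALSE, decision_group = 1,
                trigger = NA_character_, diagnosed = TRUE, pcc_final = pcc1,
                predicted = cls0$predicted))
  }
  prof <- models$profiles
  sim_pcc <- function(polarity) {
    rec <- record_corrected
    for (a in c("ab42", "total_tau", "p_tau")) {
      rec[[a]] <- prof[[a]][prof$polarity == polarity]
    }
    cls <- suppressWarnings(dsi_classify(rec, models$dsi_csf))
    estimate_pcc(models$pcc_csf, cls$d1, cls$margin)$value
  }
  pcc_pos <- sim_pcc("positive")
  pcc_neg <- sim_pcc("negative")
  trigger <- if (pcc_pos >= thr && pcc_neg >= thr) "both"
  else if (pcc_pos >= thr) "positive_only"
  else if (pcc_neg >= thr) "negative_only"
  else "none"
  if (trigger == "none") {
    return(list(csf_tested = FALSE, decision_group = 2, trigger = "none",
                diagnosed = FALSE, pcc_final = pcc1,
                predicted = cls0$predicted))
  }
  cls_act <- suppressWarnings(dsi_classify(record_corrected, models$dsi_csf))
  pcc_act <- estimate_pcc(models$pcc_csf, cls_act$d1, cls_act$margin)$value
  list(csf_tested = TRUE,
       decision_group = if (pcc_act >= thr) 3 else 4,
       trigger = trigger, diagnosed = pcc_act >= thr,
       pcc_final = pcc_act, predicted = cls_act$predicted)
}

# Small labeled random cohort builder for oracle-equivalence tests:
# n per group, a handful of continuous features, optional missingness.
oracle_test_cohort <- function(n_per_group, seed, miss_rate = 0) {
  withr::with_seed(seed, {
    groups <- rep(c("CONTROL", "AD", "FTD", "VAD"), each = n_per_group)
    n <- length(groups)
    shift <- match(groups, c("CONTROL", "AD", "FTD", "VAD"))
    df <- tibble::tibble(
      patient_id = sprintf("T%03d", seq_len(n)),
      age = runif(n, 50, 80),
      sex = sample(c("F", "M"), n, replace = TRUE),
      diagnosis = groups,
      mmse = pmin(pmax(30 - 2 * shift + rnorm(n, 0, 2), 0), 30),
      tmt_a = pmax(30 + 15 * shift + rnorm(n, 0, 20), 0),
      ab42 = pmax(1000 - 120 * shift + rnorm(n, 0, 150), 0)
    )
    for (f in c("mmse", "tmt_a", "ab42")) {
      df[[f]][runif(n) < miss_rate] <- NA
    }
    as_cohort(df, corrected = TRUE)
  })
}
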