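#' Summarize scenario outcomes
#'
#' Per-scenario counts and nearest-integer percentages of patients with
#' CSF tested and patients diagnosed with sufficient confidence, plus
#' the classification accuracy among the diagnosed — the scenario
#' comparison table of the triage analysis.
#'
#' @param outcomes A [run_scenarios()] outcome tibble (any subset of
#'   scenarios; all must cover the same patients).
#' @param labels Clinical diagnoses: either a named character vector
#'   (names = patient ids) or a labeled cohort tibble.
#' @return A tibble with one row per scenario: `scenario`, `n_total`,
#'   `n_tested`, `pct_tested`, `n_diagnosed`, `pct_diagnosed`,
#'   `accuracy_among_diagnosed`.  Percentages are rounded to the
#'   nearest integer, halves away from zero.
#' @export
summarize_scenarios <- function(outcomes, labels) {
  if (is.data.frame(labels)) {
    labels <- stats::setNames(labels$diagnosis, labels$patient_id)
  }
  ids_by_scenario <- split(outcomes$patient_id, outcomes$scenario)
  ref_ids <- sort(ids_by_scenario[[1]])
  same <- vapply(ids_by_scenario, function(x) identical(sort(x), ref_ids),
                 logical(1))
  if (!all(same)) {
    stop("scenarios were run on mismatched cohorts", call. = FALSE)
  }
  outcomes |>
    dplyr::group_by(.data$scenario) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_tested = sum(.data$csf_tested),
      pct_tested = round_half_away(100 * .data$n_tested / .data$n_total),
      n_diagnosed = sum(.data$diagnosed),
      pct_diagnosed = round_half_away(100 * .data$n_diagnosed / .data$n_total),
      accuracy_among_diagnosed = if (any(.data$diagnosed)) {
        mean(.data$predicted[.data$diagnosed] ==
               labels[.data$patient_id[.data$diagnosed]])
      } else NA_real_,
      .groups = "drop"
    )
}

#' Round to nearest integer, halves away from zero
#'
#' The rounding convention used for all printed percentages (base R's
#' `round()` rounds halves to even).
#'
#' @param x Numeric vector.
#' @return Numeric vector of integers.
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Two-sample test of proportions
#'
#' Compares two proportions `x1/n1` and `x2/n2`: the z statistic uses
#' the pooled-variance standard error, the 95% confidence interval the
#' unpooled (Wald) standard error, no continuity correction.  The
#' difference and CI are reported in percentage points.
#'
#' @param x1,n1,x2,n2 Successes and totals of the two samples.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: `diff` (percentage points), `ci_low`,
#'   `ci_high`, `z`, `p` (two-sided normal).
#' @examples
#' two_sample_proportion_test(379, 535, 308, 535)  # diff rounds to 13
#' @export
two_sample_proportion_test <- function(x1, n1, x2, n2, conf_level = 0.95) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1
  p2 <- x2 / n2
  diff <- 100 * (p1 - p2)
  pp <- (x1 + x2) / (n1 + n2)
  se_pooled <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se_pooled > 0) (p1 - p2) / se_pooled else 0
  p <- if (se_pooled > 0) 2 * stats::pnorm(-abs(z)) else 1
  se_wald <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    diff = diff,
    ci_low = diff - 100 * zc * se_wald,
    ci_high = diff + 100 * zc * se_wald,
    z = z, p = p
  )
}

#' Characterize the stepwise-scenario decision groups
#'
#' Baseline characteristics of the four decision groups of the stepwise
#' scenario (directly diagnosed / CSF predicted unhelpful / diagnosed
#' after CSF / tested but undiagnosed): per group n, mean and SD of the
#' continuous variables, counts and percentages of the categorical
#' ones, the margin to the second DSI without CSF, and the share
#' meeting the appropriate-use criterion (no-CSF DSI for AD > 0.6).
#' Across-group p-values use one-way ANOVA for continuous variables and
#' the chi-square test for categorical ones; when any group has fewer
#' than 2 members the p-value is reported as `NA`.
#'
#' @param cohort The (raw or corrected) cohort the scenario was run on;
#'   means/SDs are reported on the scale of this table.
#' @param outcomes Scenario-A rows of a [run_scenarios()] result.
#' @return A long tibble: `variable`, `label`, `type`, `decision_group`,
#'   `n`, `mean`, `sd`, `count`, `pct`, `statistic`, `p_value`
#'   (statistic/p repeated across the variable's rows).
#' @export
group_characteristics <- function(cohort, outcomes) {
  oc <- outcomes[outcomes$scenario == "A", ]
  if (nrow(oc) == 0) stop("no scenario-A outcomes supplied", call. = FALSE)
  dat <- dplyr::inner_join(
    tibble::as_tibble(cohort),
    oc[, c("patient_id", "decision_group", "margin_nocsf", "dsi_ad_nocsf")],
    by = "patient_id"
  )
  dat$female <- as.double(dat$sex == "F")
  dat$auc_positive <- as.double(dat$dsi_ad_nocsf > 0.6)
  grp <- factor(dat$decision_group, levels = 1:4)
  # a represented group with a single member blocks the across-group
  # tests; empty groups are simply absent from them
  gtab <- table(grp)
  small_groups <- any(gtab > 0 & gtab < 2)

  cat <- feature_catalog()
  cont_feats <- intersect(cat$name[cat$kind == "continuous"], names(dat))
  cont_vars <- c("age", cont_feats, "margin_nocsf")
  cont_labels <- c("Age, years",
                   cat$label[match(cont_feats, cat$name)],
                   "Difference with second DSI without CSF")
  bin_vars <- c("female", intersect("apoe_e4", names(dat)), "auc_positive")
  bin_labels <- c("Female",
                  if ("apoe_e4" %in% names(dat)) "APOE e4 carrier",
                  "AUC+ (DSI for AD > 0.6)")

  anova_p <- function(v) {
    ok <- !is.na(v)
    g <- droplevels(grp[ok])
    if (small_groups || nlevels(g) < 2 || sum(ok) < 5) {
      return(c(NA_real_, NA_real_))
    }
    tab <- summary(stats::aov(v[ok] ~ g))[[1]]
    c(tab$`F value`[1], tab$`Pr(>F)`[1])
  }
  chisq_p <- function(v) {
    if (small_groups) return(c(NA_real_, NA_real_))
    tab <- table(droplevels(grp[!is.na(v)]), v[!is.na(v)])
    if (ncol(tab) < 2 || nrow(tab) < 2) return(c(0, 1))
    ct <- suppressWarnings(stats::chisq.test(tab))
    c(unname(ct$statistic), unname(ct$p.value))
  }

  rows <- list()
  for (i in seq_along(cont_vars)) {
    v <- dat[[cont_vars[i]]]
    st <- anova_p(v)
    rows[[length(rows) + 1]] <- tibble::tibble(
      variable = cont_vars[i], label = cont_labels[i], type = "continuous",
      decision_group = 1:4,
      n = as.integer(tapply(!is.na(v), grp, sum, default = 0L)),
      mean = as.numeric(tapply(v, grp, mean, na.rm = TRUE)),
      sd = as.numeric(tapply(v, grp, stats::sd, na.rm = TRUE)),
      count = NA_integer_, pct = NA_real_,
      statistic = st[1], p_value = st[2]
    )
  }
  for (i in seq_along(bin_vars)) {
    v <- dat[[bin_vars[i]]]
    st <- chisq_p(v)
    nobs <- as.integer(tapply(!is.na(v), grp, sum, default = 0L))
    cnt <- as.integer(tapply(v, grp, function(x) sum(x, na.rm = TRUE),
                             default = 0L))
    rows[[length(rows) + 1]] <- tibble::tibble(
      variable = bin_vars[i], label = bin_labels[i], type = "binary",
      decision_group = 1:4,
      n = nobs, mean = NA_real_, sd = NA_real_,
      count = cnt, pct = ifelse(nobs > 0, 100 * cnt / nobs, NA_real_),
      statistic = st[1], p_value = st[2]
    )
  }
  dx <- factor(dat$diagnosis, diagnosis_levels())
  st <- if (small_groups) c(NA_real_, NA_real_) else {
    ct <- suppressWarnings(stats::chisq.test(table(droplevels(grp),
                                                   droplevels(dx))))
    c(unname(ct$statistic), unname(ct$p.value))
  }
  for (lev in diagnosis_levels()) {
    v <- as.double(dx == lev)
    nobs <- as.integer(tapply(!is.na(v), grp, sum, default = 0L))
    cnt <- as.integer(tapply(v, grp, sum, default = 0L))
    rows[[length(rows) + 1]] <- tibble::tibble(
      variable = paste0("diagnosis_", lev),
      label = paste0("Clinical diagnosis: ", lev), type = "binary",
      decision_group = 1:4,
      n = nobs, mean = NA_real_, sd = NA_real_,
      count = cnt, pct = ifelse(nobs > 0, 100 * cnt / nobs, NA_real_),
      statistic = st[1], p_value = st[2]
    )
  }
  dplyr::bind_rows(rows)
}
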