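#' Simulated positive and negative CSF biomarker profiles
#'
#' The scenario engine asks "what would knowing CSF do for this
#' patient?" before any lumbar puncture, by substituting two canonical
#' profiles: a positive (AD-like) profile — the per-analyte medians of
#' the AD group's age- and sex-corrected AB42, total tau and p-tau —
#' and a negative (normal) profile — the medians of the control (SCD)
#' group.  Profiles always carry all three analytes; a profile is never
#' substituted partially.
#'
#' @param reference A corrected, labeled cohort.
#' @param min_ref Minimum observed CSF values per group (default 5).
#' @return A tibble with rows `positive` and `negative`: `polarity`,
#'   `ab42`, `total_tau`, `p_tau`.
#' @export
simulated_csf_profiles <- function(reference, min_ref = 5) {
  stopifnot_corrected(reference, "simulated_csf_profiles()")
  med <- function(group, analyte) {
    v <- reference[[analyte]][!is.na(reference$diagnosis) &
                                reference$diagnosis == group]
    v <- v[!is.na(v)]
    if (length(v) < min_ref) {
      stop(sprintf(
        "group %s has only %d observed '%s' values (need >= %d)",
        group, length(v), analyte, min_ref
      ), call. = FALSE)
    }
    stats::median(v)
  }
  tibble::tibble(
    polarity = c("positive", "negative"),
    ab42 = c(med("AD", "ab42"), med("CONTROL", "ab42")),
    total_tau = c(med("AD", "total_tau"), med("CONTROL", "total_tau")),
    p_tau = c(med("AD", "p_tau"), med("CONTROL", "p_tau"))
  )
}

#' Fit the full bundle of triage models from one reference cohort
#'
#' Convenience constructor for everything [run_scenarios()] needs: DSI
#' and PCC models for the no-CSF and with-CSF feature subsets, plus the
#' simulated CSF profiles, all from one corrected labeled reference.
#'
#' @param reference A corrected, labeled cohort.
#' @param k Neighborhood size for both PCC models (default as in
#'   [fit_pcc()]).
#' @param min_ref Minimum reference observations (default 5).
#' @return A list of class `triage_models`: `dsi_nocsf`, `dsi_csf`,
#'   `pcc_nocsf`, `pcc_csf`, `profiles`, `reference_ids`.
#' @export
fit_triage_models <- function(reference, k = NULL, min_ref = 5) {
  stopifnot_corrected(reference, "fit_triage_models()")
  structure(
    list(
      dsi_nocsf = fit_dsi(reference, feature_subset("nocsf"), min_ref),
      dsi_csf = fit_dsi(reference, feature_subset("csf"), min_ref),
      pcc_nocsf = fit_pcc(reference, feature_subset("nocsf"), k, min_ref),
      pcc_csf = fit_pcc(reference, feature_subset("csf"), k, min_ref),
      profiles = simulated_csf_profiles(reference, min_ref),
      reference_ids = reference$patient_id
    ),
    class = "triage_models"
  )
}

#' Per-patient triage evaluation
#'
#' Computes every threshold-free quantity the four scenarios need, one
#' row per patient: PCC and prediction from the no-CSF models, the
#' no-CSF DSI for AD (the appropriate-use-criteria gate), the two
#' simulated-CSF PCCs (positive and negative profile substituted into
#' the corrected record, evaluated under the with-CSF models), and the
#' PCC/prediction with the patient's actual CSF values.  Scenario
#' decisions at any PCC cutoff are pure thresholding of this table,
#' which is what makes cutoff sweeps cheap.
#'
#' @param cohort A corrected cohort (query patients; may equal the
#'   models' reference, in which case results are optimistic and a
#'   warning is raised).
#' @param models A `triage_models` bundle.
#' @return A tibble with columns `patient_id`, `diagnosis`,
#'   `pcc_nocsf`, `predicted_nocsf`, `d1_nocsf`, `margin_nocsf`,
#'   `dsi_ad_nocsf`, `pcc_sim_positive`, `pcc_sim_negative`,
#'   `pcc_csf`, `predicted_csf`, `csf_complete`, `csf_missing`.
#' @export
triage_evaluate <- function(cohort, models) {
  stopifnot_corrected(cohort, "triage_evaluate()")
  if (any(cohort$patient_id %in% models$reference_ids)) {
    warning("cohort overlaps the models' reference; ",
            "PCC values will be optimistic", call. = FALSE)
  }
  analytes <- csf_analytes()
  prof <- models$profiles
  pos_prof <- as.list(prof[prof$polarity == "positive", analytes])
  neg_prof <- as.list(prof[prof$polarity == "negative", analytes])

  feats_csf <- models$dsi_csf$features
  n <- nrow(cohort)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    vals_csf <- record_values(cohort, i, feats_csf)

    ev0 <- dsi_eval_record(models$dsi_nocsf,
                           vals_csf[models$dsi_nocsf$features])
    vals_pos <- utils::modifyList(vals_csf, pos_prof)
    vals_neg <- utils::modifyList(vals_csf, neg_prof)
    evp <- dsi_eval_record(models$dsi_csf, vals_pos)
    evn <- dsi_eval_record(models$dsi_csf, vals_neg)
    eva <- dsi_eval_record(models$dsi_csf, vals_csf)

    missing_csf <- analytes[vapply(vals_csf[analytes], is.na, logical(1))]
    out[[i]] <- tibble::tibble(
      patient_id = cohort$patient_id[i],
      diagnosis = cohort$diagnosis[i],
      d1_nocsf = ev0$d1, margin_nocsf = ev0$margin,
      dsi_ad_nocsf = ev0$totals[["AD"]],
      predicted_nocsf = ev0$predicted,
      d1_sim_positive = evp$d1, margin_sim_positive = evp$margin,
      d1_sim_negative = evn$d1, margin_sim_negative = evn$margin,
      d1_csf = eva$d1, margin_csf = eva$margin,
      predicted_csf = eva$predicted,
      csf_complete = length(missing_csf) == 0,
      csf_missing = paste(missing_csf, collapse = ",")
    )
  }
  ev <- dplyr::bind_rows(out)

  ev$pcc_nocsf <- estimate_pcc(models$pcc_nocsf, ev$d1_nocsf,
                               ev$margin_nocsf)$value
  ev$pcc_sim_positive <- estimate_pcc(models$pcc_csf, ev$d1_sim_positive,
                                      ev$margin_sim_positive)$value
  ev$pcc_sim_negative <- estimate_pcc(models$pcc_csf, ev$d1_sim_negative,
                                      ev$margin_sim_negative)$value
  ev$pcc_csf <- estimate_pcc(models$pcc_csf, ev$d1_csf, ev$margin_csf)$value
  ev
}

# Scenario decisions from a triage_evaluate() table at one cutoff.
scenario_from_eval <- function(ev, scenario, pcc_threshold,
                               auc_dsi_ad_threshold) {
  n <- nrow(ev)
  base <- tibble::tibble(
    patient_id = ev$patient_id, scenario = scenario,
    csf_tested = FALSE,
    pcc_step1 = ev$pcc_nocsf,
    pcc_sim_positive = NA_real_, pcc_sim_negative = NA_real_,
    trigger = NA_character_,
    pcc_final = NA_real_, predicted = NA_character_,
    diagnosed = FALSE, decision_group = NA_integer_,
    margin_nocsf = ev$margin_nocsf, dsi_ad_nocsf = ev$dsi_ad_nocsf
  )

  require_csf <- function(tested) {
    bad <- which(tested & !ev$csf_complete)
    if (length(bad) > 0) {
      stop(sprintf(
        "patient %s requires actual CSF values but lacks analyte(s): %s",
        ev$patient_id[bad[1]], ev$csf_missing[bad[1]]
      ), call. = FALSE)
    }
  }

  if (scenario == "A") {
    step1 <- ev$pcc_nocsf >= pcc_threshold
    sim_pos <- ev$pcc_sim_positive >= pcc_threshold
    sim_neg <- ev$pcc_sim_negative >= pcc_threshold
    tested <- !step1 & (sim_pos | sim_neg)
    require_csf(tested)
    base$csf_tested <- tested
    base$pcc_sim_positive <- ifelse(step1, NA_real_, ev$pcc_sim_positive)
    base$pcc_sim_negative <- ifelse(step1, NA_real_, ev$pcc_sim_negative)
    base$trigger <- ifelse(step1, NA_character_,
                           ifelse(sim_pos & sim_neg, "both",
                                  ifelse(sim_pos, "positive_only",
                                         ifelse(sim_neg, "negative_only",
                                                "none"))))
    base$pcc_final <- ifelse(tested, ev$pcc_csf, ev$pcc_nocsf)
    base$predicted <- ifelse(tested, ev$predicted_csf, ev$predicted_nocsf)
    base$diagnosed <- base$pcc_final >= pcc_threshold
    base$decision_group <- dplyr::case_when(
      step1 ~ 1L,
      !tested ~ 2L,
      base$diagnosed ~ 3L,
      TRUE ~ 4L
    )
  } else if (scenario == "B") {
    base$pcc_final <- ev$pcc_nocsf
    base$predicted <- ev$predicted_nocsf
    base$diagnosed <- base$pcc_final >= pcc_threshold
  } else if (scenario == "C") {
    tested <- ev$dsi_ad_nocsf > auc_dsi_ad_threshold
    require_csf(tested)
    base$csf_tested <- tested
    base$pcc_final <- ifelse(tested, ev$pcc_csf, ev$pcc_nocsf)
    base$predicted <- ifelse(tested, ev$predicted_csf, ev$predicted_nocsf)
    base$diagnosed <- base$pcc_final >= pcc_threshold
  } else if (scenario == "D") {
    # missing actual CSF is carried, flagged, with PCC from available
    # data, mirroring the classifier's missing-data tolerance
    base$csf_tested <- TRUE
    base$pcc_final <- ev$pcc_csf
    base$predicted <- ev$predicted_csf
    base$diagnosed <- base$pcc_final >= pcc_threshold
  } else {
    stop("unknown scenario: ", scenario, call. = FALSE)
  }
  base$csf_incomplete <- base$csf_tested & !ev$csf_complete
  base
}

#' Run the four diagnostic scenarios
#'
#' Scenario A ("computerized decision support") is the stepwise policy:
#' step one, patients with no-CSF PCC at or above the threshold are
#' diagnosed directly and no CSF is ordered (decision group 1).  Step
#' two, for the rest both simulated CSF profiles are substituted; if
#' neither pushes the with-CSF PCC over the threshold, CSF is predicted
#' unhelpful and not ordered (group 2).  Step three, otherwise actual
#' CSF values are used; the final PCC decides between diagnosed (group
#' 3) and tested-but-undiagnosed (group 4, suggestive of mixed
#' pathology).  Scenario B uses no CSF for anyone, scenario C orders
#' CSF according to the appropriate-use criteria operationalized as
#' no-CSF DSI for AD above `auc_dsi_ad_threshold`, and scenario D
#' orders CSF for everyone.
#'
#' @param cohort A corrected cohort, or a `triage_evaluate()` table.
#' @param models A `triage_models` bundle (ignored when `cohort` is
#'   already an evaluation table).
#' @param scenarios Which scenarios to run (default all four).
#' @param pcc_threshold PCC needed to count as diagnosed with
#'   sufficient confidence (default 0.80).
#' @param auc_dsi_ad_threshold Appropriate-use-criteria gate on the
#'   no-CSF DSI for AD (default 0.6).
#' @return A tibble with one row per patient per scenario:
#'   `patient_id`, `scenario`, `csf_tested`, `pcc_step1`,
#'   `pcc_sim_positive`, `pcc_sim_negative`, `trigger`
#'   (`positive_only`/`negative_only`/`both`/`none`, `NA` when no
#'   simulation was run), `pcc_final`, `predicted`, `diagnosed`,
#'   `decision_group` (1-4, scenario A only), `margin_nocsf`,
#'   `dsi_ad_nocsf`, `csf_incomplete`.
#' @export
run_scenarios <- function(cohort, models = NULL,
                          scenarios = c("A", "B", "C", "D"),
                          pcc_threshold = 0.80,
                          auc_dsi_ad_threshold = 0.6) {
  stopifnot(pcc_threshold > 0, pcc_threshold < 1)
  ev <- if (is_triage_eval(cohort)) cohort else triage_evaluate(cohort, models)
  dplyr::bind_rows(lapply(scenarios, function(s) {
    scenario_from_eval(ev, s, pcc_threshold, auc_dsi_ad_threshold)
  }))
}

is_triage_eval <- function(x) {
  is.data.frame(x) && all(c("pcc_nocsf", "pcc_sim_positive", "pcc_csf")
                          %in% names(x))
}

#' Sweep the PCC cutoff over a grid
#'
#' Reruns all four scenarios at each cutoff of the grid and reports,
#' per scenario and cutoff, the share of patients with CSF tested, the
#' share diagnosed with sufficient confidence, and the classification
#' accuracy among the diagnosed.
#'
#' @inheritParams run_scenarios
#' @param cutoffs Numeric grid of PCC cutoffs (default 0.5 to 1.0 in
#'   steps of 0.05).
#' @return A tibble of class `triage_sweep`: `cutoff`, `scenario`,
#'   `share_tested`, `share_diagnosed`, `accuracy_among_diagnosed`
#'   (`NA` when nobody is diagnosed at that cutoff).
#' @export
sweep_pcc_cutoffs <- function(cohort, models = NULL,
                              cutoffs = seq(0.5, 1.0, by = 0.05),
                              scenarios = c("A", "B", "C", "D"),
                              auc_dsi_ad_threshold = 0.6) {
  ev <- if (is_triage_eval(cohort)) cohort else triage_evaluate(cohort, models)
  labels <- stats::setNames(ev$diagnosis, ev$patient_id)
  out <- purrr::map_dfr(cutoffs, function(ct) {
    thr <- min(max(ct, 1e-9), 1 - 1e-9)
    purrr::map_dfr(scenarios, function(s) {
      o <- scenario_from_eval(ev, s, thr, auc_dsi_ad_threshold)
      diag <- o$diagnosed
      tibble::tibble(
        cutoff = ct, scenario = s,
        share_tested = mean(o$csf_tested),
        share_diagnosed = mean(diag),
        accuracy_among_diagnosed = if (any(diag)) {
          mean(o$predicted[diag] == labels[o$patient_id[diag]])
        } else NA_real_
      )
    })
  })
  class(out) <- c("triage_sweep", class(out))
  out
}
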