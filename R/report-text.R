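#' Plain-text triage report for one patient
#'
#' A deterministic textual rendering of the stepwise decision support
#' for a single patient: the per-group Disease State Index without CSF,
#' the step-one PCC, the PCC under both simulated CSF profiles, the
#' recommendation whether CSF measurement is considered potentially
#' useful, and — when CSF was (to be) tested and actual values are
#' available — the post-CSF DSI profile and final PCC.
#'
#' @param cohort A corrected cohort containing the patient.
#' @param models A `triage_models` bundle.
#' @param patient_id Id of the patient to report on.
#' @param pcc_threshold Confidence cutoff (default 0.80).
#' @return A single character string (the report), invisibly also
#'   printed when `print = TRUE`.
#' @param print Print the report to the console (default `FALSE`).
#' @export
patient_report <- function(cohort, models, patient_id,
                           pcc_threshold = 0.80, print = FALSE) {
  row <- which(cohort$patient_id == patient_id)
  if (length(row) != 1) {
    stop("patient '", patient_id, "' not found in cohort", call. = FALSE)
  }
  one <- cohort[row, , drop = FALSE]
  ev <- suppressWarnings(triage_evaluate(one, models))
  oc <- scenario_from_eval(ev, "A", pcc_threshold, 0.6)

  cls0 <- suppressWarnings(dsi_classify(one, models$dsi_nocsf))
  fmt_profile <- function(cls) {
    paste(sprintf("%s %.2f", diagnosis_levels(),
                  c(cls$dsi_CONTROL, cls$dsi_AD, cls$dsi_FTD, cls$dsi_VAD)),
          collapse = " | ")
  }

  lines <- c(
    "==========================================================",
    sprintf(" CSF biomarker triage report - patient %s", patient_id),
    "==========================================================",
    sprintf(" PCC threshold for sufficient confidence: %.2f",
            pcc_threshold),
    "",
    " Step 1 - neuropsychology, MRI and APOE only",
    sprintf("   DSI: %s", fmt_profile(cls0)),
    sprintf("   Suggested diagnosis: %-7s (margin to second: %.2f)",
            ev$predicted_nocsf, ev$margin_nocsf),
    sprintf("   Probability of correct class: %.2f", ev$pcc_nocsf)
  )

  if (oc$decision_group == 1) {
    lines <- c(lines, "",
               sprintf(" Directly diagnosed without CSF (PCC %.2f >= %.2f);",
                       ev$pcc_nocsf, pcc_threshold),
               " no CSF simulation performed.")
  } else {
    lines <- c(
      lines, "",
      " Step 2 - simulated CSF biomarker profiles",
      sprintf("   AD-like profile -> PCC %.2f", ev$pcc_sim_positive),
      sprintf("   Normal profile  -> PCC %.2f", ev$pcc_sim_negative),
      if (oc$csf_tested) {
        " Recommendation: CSF measurement is considered potentially useful."
      } else {
        " Recommendation: CSF measurement is not considered useful."
      }
    )
    if (oc$csf_tested && ev$csf_complete) {
      clsc <- suppressWarnings(dsi_classify(one, models$dsi_csf))
      lines <- c(
        lines, "",
        " Step 3 - actual CSF biomarker values",
        sprintf("   DSI: %s", fmt_profile(clsc)),
        sprintf("   Suggested diagnosis: %-7s (margin to second: %.2f)",
                ev$predicted_csf, ev$margin_csf),
        sprintf("   Probability of correct class: %.2f", ev$pcc_csf),
        sprintf("   %s", if (oc$diagnosed) {
          "Diagnosis reached with sufficient confidence."
        } else {
          "Confidence remains insufficient (suggestive of mixed pathology)."
        })
      )
    }
  }
  lines <- c(lines,
             "",
             sprintf(" Decision group: %d", oc$decision_group),
             "==========================================================")
  report <- paste(lines, collapse = "\n")
  if (print) {
    cat(report, "\n")
    return(invisible(report))
  }
  report
}
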