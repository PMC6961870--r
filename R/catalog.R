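#' Feature catalog for the memory-clinic cohort schema
#'
#' The fixed inventory of classifier features: name, modality
#' (neuropsychology, MRI, APOE genotype or CSF biomarker), measurement
#' kind and the plausible range used for input validation.  Values
#' outside the plausible range are rejected at read time, never clamped.
#'
#' @return A tibble with columns `name`, `modality` (one of `"NP"`,
#'   `"MRI"`, `"APOE"`, `"CSF"`), `kind` (`"continuous"` or `"binary"`),
#'   `lower`, `upper` (closed plausible interval, units per feature) and
#'   a human-readable `label`.
#' @examples
#' feature_catalog()
#' @export
feature_catalog <- function() {
  tibble::tribble(
    ~name,            ~modality, ~kind,        ~lower, ~upper, ~label,
    "apoe_e4",        "APOE",    "binary",          0,      1, "APOE e4 carrier",
    "mmse",           "NP",      "continuous",      0,     30, "MMSE",
    "ravlt_learning", "NP",      "continuous",      0,     75, "RAVLT, learning",
    "ravlt_recall",   "NP",      "continuous",      0,     15, "RAVLT, recall",
    "tmt_a",          "NP",      "continuous",      0,    600, "TMT-A, seconds",
    "tmt_b",          "NP",      "continuous",      0,   1200, "TMT-B, seconds",
    "animal_fluency", "NP",      "continuous",      0,     60, "Animal fluency",
    "npi_total",      "NP",      "continuous",      0,    144, "NPI, total score",
    "cmta_right",     "MRI",     "continuous",      0,      4, "cMTA right",
    "cmta_left",      "MRI",     "continuous",      0,      4, "cMTA left",
    "cgca",           "MRI",     "continuous",      0,      3, "cGCA",
    "wmh_ml",         "MRI",     "continuous",      0,    500, "WMH, ml",
    "ad_similarity",  "MRI",     "continuous",      0,      1, "AD similarity scale",
    "ap_index",       "MRI",     "continuous",    -10,     10, "Anterior-Posterior index",
    "ab42",           "CSF",     "continuous",      0,   3000, "AB42, pg/ml",
    "total_tau",      "CSF",     "continuous",      0,   3000, "Total tau, pg/ml",
    "p_tau",          "CSF",     "continuous",      0,    500, "P-tau, pg/ml"
  )
}

#' Diagnostic groups and canonical group pairs
#'
#' The four diagnostic groups, in the fixed tie-break order used
#' throughout the package, and the six canonical group pairs over which
#' pairwise Disease State Index comparisons are fitted.  Reversed pairs
#' are obtained by the complement `1 - DSI`, never refitted.
#'
#' @return `diagnosis_levels()`: a character vector
#'   `c("CONTROL", "AD", "FTD", "VAD")`.  `canonical_pairs()`: a tibble
#'   with columns `positive` and `negative`.
#' @export
diagnosis_levels <- function() c("CONTROL", "AD", "FTD", "VAD")

#' @rdname diagnosis_levels
#' @export
canonical_pairs <- function() {
  tibble::tribble(
    ~positive, ~negative,
    "CONTROL", "AD",
    "CONTROL", "FTD",
    "CONTROL", "VAD",
    "AD",      "FTD",
    "AD",      "VAD",
    "VAD",     "FTD"
  )
}

#' Standard feature subsets
#'
#' The two feature subsets the triage workflow compares: everything
#' except CSF biomarkers (`"nocsf"`: neuropsychology, MRI and APOE, the
#' data available before lumbar puncture) and the full set including the
#' three CSF analytes (`"csf"`).
#'
#' @param which `"nocsf"`, `"csf"` or `"all"` (alias for `"csf"`).
#' @return Character vector of feature names.
#' @examples
#' feature_subset("nocsf")
#' @export
feature_subset <- function(which = c("nocsf", "csf", "all")) {
  which <- match.arg(which)
  cat <- feature_catalog()
  if (which == "nocsf") cat$name[cat$modality != "CSF"] else cat$name
}

csf_analytes <- function() c("ab42", "total_tau", "p_tau")

id_columns <- function() c("patient_id", "age", "sex", "diagnosis")
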