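#' Validate a data frame as a patient cohort
#'
#' A cohort is a tibble with one row per patient and columns
#' `patient_id`, `age`, `sex` (`"F"`/`"M"`), `diagnosis` (`CONTROL`,
#' `AD`, `FTD`, `VAD`, or `NA` for unlabeled query patients) followed by
#' the features of [feature_catalog()].  Missing measurements are `NA`;
#' the classifier tolerates them, so no imputation is ever performed.
#' Whether values have been age/sex-corrected is tracked in the
#' `corrected` attribute (see [apply_covariate_correction()]).
#'
#' @param df A data frame in the cohort schema.
#' @param corrected Logical; mark the cohort as already covariate
#'   corrected.  Range validation is skipped for corrected values, since
#'   residualization can legitimately move values outside the raw
#'   plausible range.
#' @return A validated cohort tibble with the `corrected` attribute set.
#' @export
as_cohort <- function(df, corrected = FALSE) {
  cat <- feature_catalog()
  df <- tibble::as_tibble(df)

  required <- id_columns()
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(df), c(required, cat$name))
  if (length(unknown) > 0) {
    stop("unknown column(s) not in the feature catalog: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  df$patient_id <- as.character(df$patient_id)
  dup <- df$patient_id[duplicated(df$patient_id)]
  if (length(dup) > 0) {
    stop("duplicate patient_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(df$patient_id)) stop("patient_id must not be missing", call. = FALSE)
  if (anyNA(df$age) || any(df$age <= 0)) {
    stop("age must be present and positive for every patient", call. = FALSE)
  }
  if (anyNA(df$sex) || !all(df$sex %in% c("F", "M"))) {
    stop("sex must be present and one of 'F', 'M'", call. = FALSE)
  }
  bad_dx <- !is.na(df$diagnosis) & !(df$diagnosis %in% diagnosis_levels())
  if (any(bad_dx)) {
    stop("invalid diagnosis label(s): ",
         paste(unique(df$diagnosis[bad_dx]), collapse = ", "), call. = FALSE)
  }

  for (f in intersect(cat$name, names(df))) {
    df[[f]] <- as.double(df[[f]])
    spec <- cat[cat$name == f, ]
    v <- df[[f]]
    if (spec$kind == "binary") {
      bad <- which(!is.na(v) & !(v %in% c(0, 1)))
    } else if (!corrected) {
      bad <- which(!is.na(v) & (v < spec$lower | v > spec$upper))
    } else {
      bad <- integer(0)
    }
    if (length(bad) > 0) {
      stop(sprintf(
        "value out of plausible range [%g, %g] for '%s' in row %d (patient %s): %g",
        spec$lower, spec$upper, f, bad[1], df$patient_id[bad[1]], v[bad[1]]
      ), call. = FALSE)
    }
  }

  attr(df, "corrected") <- isTRUE(corrected)
  df
}

cohort_corrected <- function(cohort) isTRUE(attr(cohort, "corrected"))

cohort_features <- function(cohort) {
  intersect(feature_catalog()$name, names(cohort))
}

stopifnot_corrected <- function(cohort, what = "this operation") {
  if (!cohort_corrected(cohort)) {
    stop(what, " requires a covariate-corrected cohort; ",
         "run apply_covariate_correction() first", call. = FALSE)
  }
  invisible(cohort)
}

#' Read and write cohorts as CSV
#'
#' One row per patient; empty cells denote missing values.  Values are
#' validated against the plausible ranges of [feature_catalog()] and
#' rejected (never clamped) when out of range.
#'
#' @param path Path to a CSV file.
#' @param corrected Logical; whether the file holds covariate-corrected
#'   values (skips range validation).
#' @return `read_cohort()`: a cohort tibble.  `write_cohort()`: `path`,
#'   invisibly.
#' @export
read_cohort <- function(path, corrected = FALSE) {
  header <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  cat <- feature_catalog()
  unknown <- setdiff(header, c(id_columns(), cat$name))
  if (length(unknown) > 0) {
    stop("unknown column(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  types <- readr::cols(
    patient_id = readr::col_character(),
    sex = readr::col_character(),
    diagnosis = readr::col_character(),
    .default = readr::col_double()
  )
  df <- readr::read_csv(path, col_types = types, na = "", progress = FALSE)
  as_cohort(df, corrected = corrected)
}

#' @param cohort A cohort tibble.
#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}
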