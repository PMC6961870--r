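#' Fit age/sex covariate models on a reference group
#'
#' Every continuous feature is residualized for age and sex before it
#' enters the Disease State Index machinery.  One ordinary least-squares
#' model `value ~ age + sex` is fitted per continuous feature on the
#' observed values of the reference group (controls by default, so that
#' disease effects are not absorbed into the correction).  Sex is coded
#' 0 = male, 1 = female.  Binary features (APOE carrier status) are
#' excluded: a residualized indicator loses its meaning as evidence.
#'
#' @param cohort An uncorrected cohort tibble.
#' @param reference_group Diagnosis label whose members define the
#'   covariate models (default `"CONTROL"`).
#' @param min_obs Minimum number of usable reference observations per
#'   feature (default 10); fewer is an error naming the feature.
#' @return A tibble of class `covariate_models` with one row per
#'   continuous feature: `feature`, `intercept`, `age_coefficient`,
#'   `sex_coefficient` (female vs male), `reference_mean` (the reference
#'   group's raw mean, added back after residualization so corrected
#'   values stay on the original scale) and `n_obs`.
#' @seealso [apply_covariate_correction()]
#' @export
fit_covariate_models <- function(cohort, reference_group = "CONTROL",
                                 min_obs = 10) {
  if (cohort_corrected(cohort)) {
    stop("cohort is already covariate-corrected; fit models on raw values",
         call. = FALSE)
  }
  cat <- feature_catalog()
  features <- intersect(cat$name[cat$kind == "continuous"], names(cohort))
  ref <- cohort[!is.na(cohort$diagnosis) & cohort$diagnosis == reference_group, ]
  if (nrow(ref) == 0) {
    stop("reference group '", reference_group, "' has no members", call. = FALSE)
  }
  sex01 <- as.double(ref$sex == "F")

  models <- purrr::map(features, function(f) {
    ok <- !is.na(ref[[f]])
    if (sum(ok) < min_obs) {
      stop(sprintf(
        "feature '%s' has only %d observed reference values (need >= %d)",
        f, sum(ok), min_obs
      ), call. = FALSE)
    }
    fit <- stats::lm(y ~ age + sex01,
                     data = data.frame(y = ref[[f]][ok], age = ref$age[ok],
                                       sex01 = sex01[ok]))
    co <- stats::coef(fit)
    co[is.na(co)] <- 0  # rank-deficient design (e.g. single-sex reference)
    tibble::tibble(
      feature = f,
      intercept = unname(co["(Intercept)"]),
      age_coefficient = unname(co["age"]),
      sex_coefficient = unname(co["sex01"]),
      reference_mean = mean(ref[[f]][ok]),
      n_obs = sum(ok)
    )
  })
  out <- dplyr::bind_rows(models)
  class(out) <- c("covariate_models", class(out))
  out
}

#' Apply age/sex correction to a cohort
#'
#' Replaces every observed continuous value by
#' `value - (intercept + b_age * age + b_sex * sex) + reference_mean`,
#' i.e. the residual from the reference-group covariate model plus the
#' reference mean.  Missing values stay missing and binary features are
#' untouched.  Applying the correction twice is an error.
#'
#' @param cohort An uncorrected cohort tibble.
#' @param models A `covariate_models` tibble from [fit_covariate_models()].
#' @return The corrected cohort, with the `corrected` attribute set.
#' @export
apply_covariate_correction <- function(cohort, models) {
  if (cohort_corrected(cohort)) {
    stop("cohort is already covariate-corrected", call. = FALSE)
  }
  sex01 <- as.double(cohort$sex == "F")
  for (i in seq_len(nrow(models))) {
    f <- models$feature[i]
    if (!f %in% names(cohort)) next
    pred <- models$intercept[i] +
      models$age_coefficient[i] * cohort$age +
      models$sex_coefficient[i] * sex01
    cohort[[f]] <- cohort[[f]] - pred + models$reference_mean[i]
  }
  attr(cohort, "corrected") <- TRUE
  cohort
}

#' Fit and apply the correction in one step
#'
#' @inheritParams fit_covariate_models
#' @return A list with elements `cohort` (corrected) and `models`.
#' @export
correct_cohort <- function(cohort, reference_group = "CONTROL", min_obs = 10) {
  models <- fit_covariate_models(cohort, reference_group, min_obs)
  list(cohort = apply_covariate_correction(cohort, models), models = models)
}

#' Serialize covariate models to JSON
#'
#' @param models A `covariate_models` tibble.
#' @param path Output (input) JSON path.
#' @return `write_covariate_models()`: `path` invisibly;
#'   `read_covariate_models()`: a `covariate_models` tibble.
#' @export
write_covariate_models <- function(models, path) {
  jsonlite::write_json(as.data.frame(models), path, digits = NA,
                       auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_covariate_models
#' @export
read_covariate_models <- function(path) {
  out <- tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  class(out) <- c("covariate_models", class(out))
  out
}
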