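# Shared fitted objects, built once per test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(.cache[[key]])) assign(key, fn(), envir = .cache)
  .cache[[key]]
}

# Triage models fitted on the scenario_walk_reference fixture.
walk_setup <- function() {
  cached("walk_setup", function() {
    ref <- make_fixture("scenario_walk_reference")
    cm <- fit_covariate_models(ref)
    refc <- apply_covariate_correction(ref, cm)
    list(covariates = cm, reference = refc,
         models = fit_triage_models(refc))
  })
}

# The 12-patient walk fixture, corrected with the reference's models.
walk_cohort <- function() {
  cached("walk_cohort", function() {
    apply_covariate_correction(make_fixture("scenario_walk"),
                               walk_setup()$covariates)
  })
}

# A generated query cohort from the reference distribution, corrected.
walk_query <- function(seed) {
  cfg <- default_generator_config()
  cfg$group_sizes <- c(CONTROL = 42L, AD = 86L, FTD = 25L, VAD = 9L)
  cfg$seed <- seed
  co <- generate_cohort(cfg)
  co$patient_id <- sprintf("Q%04d", seq_len(nrow(co)))
  apply_covariate_correction(co, walk_setup()$covariates)
}
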