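#' Built-in test cohorts
#'
#' Small deterministic cohorts used throughout the test suite and the
#' documentation:
#'
#' * `"perfect_separation"` — 8 patients per group, every group
#'   occupying a disjoint value band on every continuous feature, so
#'   the classifier is error-free by construction.
#' * `"null"` — 25 patients per group drawn from the generator with
#'   `separation_scale = 0`: all four groups share one distribution and
#'   classification is at the four-class chance level.
#' * `"scenario_walk_reference"` — a 270-patient generated reference
#'   cohort (70/140/40/20) used to fit triage models in examples and
#'   tests.
#' * `"scenario_walk"` — 12 query patients, drawn from the same
#'   distribution with a different seed, whose ids were frozen so that
#'   under the companion reference and a PCC threshold of 0.80 they
#'   cover all four decision groups of the stepwise scenario.
#'
#' @param name Fixture name.
#' @return An uncorrected cohort tibble.
#' @export
make_fixture <- function(name) {
  switch(
    name,
    perfect_separation = fixture_perfect_separation(),
    null = {
      cfg <- default_generator_config()
      cfg$group_sizes[] <- 25L
      cfg$separation_scale <- 0
      cfg$seed <- 424242L
      generate_cohort(cfg)
    },
    scenario_walk_reference = {
      cfg <- default_generator_config()
      cfg$group_sizes <- c(CONTROL = 70L, AD = 140L, FTD = 40L, VAD = 20L)
      cfg$seed <- 20200115L
      generate_cohort(cfg)
    },
    scenario_walk = {
      pool <- scenario_walk_pool()
      sel <- pool[match(scenario_walk_ids(), pool$patient_id), ]
      as_cohort(sel)
    },
    stop("unknown fixture: '", name, "'; registered fixtures: ",
         "perfect_separation, null, scenario_walk, scenario_walk_reference",
         call. = FALSE)
  )
}

scenario_walk_pool <- function() {
  cfg <- default_generator_config()
  cfg$group_sizes <- c(CONTROL = 42L, AD = 86L, FTD = 25L, VAD = 9L)
  cfg$seed <- 20200116L
  pool <- generate_cohort(cfg)
  pool$patient_id <- sprintf("W%04d", seq_len(nrow(pool)))
  pool
}

# Frozen after verifying (against the straight-line scenario oracle,
# with models fitted on scenario_walk_reference at threshold 0.80) that
# the twelve cover decision groups 1-4.
scenario_walk_ids <- function() {
  c("W0001", "W0002", "W0003", "W0021", "W0138", "W0142",
    "W0028", "W0046", "W0047", "W0045", "W0058", "W0061")
}

fixture_perfect_separation <- function(n_per_group = 8) {
  groups <- diagnosis_levels()
  cat <- feature_catalog()
  cont <- cat[cat$kind == "continuous", ]
  rows <- list()
  id <- 0
  for (gi in seq_along(groups)) {
    for (j in seq_len(n_per_group)) {
      id <- id + 1
      rec <- list(
        patient_id = sprintf("P%03d", id),
        age = 55 + 2 * j,
        sex = if (j %% 2 == 0) "F" else "M",
        diagnosis = groups[gi],
        apoe_e4 = 0
      )
      for (r in seq_len(nrow(cont))) {
        lo <- cont$lower[r]
        width <- (cont$upper[r] - cont$lower[r]) / 4
        # band gi of 4, occupied in its central 80%
        rec[[cont$name[r]]] <- lo + width *
          ((gi - 1) + 0.1 + 0.8 * (j - 1) / (n_per_group - 1))
      }
      rows[[id]] <- tibble::as_tibble(rec)
    }
  }
  as_cohort(dplyr::bind_rows(rows))
}
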