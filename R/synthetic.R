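#' Default synthetic cohort generator configuration
#'
#' The generator's defaults emulate the pooled three-center memory
#' clinic cohort the method was evaluated on: four diagnostic groups
#' (139 controls with subjective cognitive decline, 286 AD, 82 FTD, 28
#' VaD), per-group feature means and SDs, per-group age distributions
#' and sex / APOE-e4 carrier frequencies, and per-feature missingness
#' rates ranging from 1% (MMSE) to 24% (TMT-B), with APOE missing in
#' 12% and MRI/CSF always present (both were inclusion criteria).
#'
#' `separation_scale` interpolates every group-specific parameter
#' toward the pooled (size-weighted) value: 1 reproduces the published
#' group profiles, 0 collapses all groups onto a single distribution
#' (a null cohort), values above 1 exaggerate the group differences.
#' `correlation` is the within-modality Gaussian-copula equicorrelation
#' between continuous features (default 0.3).
#'
#' @return A list of class `generator_config` with fields
#'   `group_sizes`, `age` (per-group mean/sd), `sex_female`,
#'   `apoe_freq`, `feature_params` (tibble: feature, group, mean, sd),
#'   `missing_rates`, `correlation`, `separation_scale`, `age_loading`,
#'   `seed`.
#' @export
default_generator_config <- function() {
  fp <- tibble::tribble(
    ~feature,          ~CONTROL_m, ~CONTROL_s, ~AD_m, ~AD_s, ~FTD_m, ~FTD_s, ~VAD_m, ~VAD_s,
    "mmse",                    28,          1,    21,     5,     24,      4,     24,      4,
    "ravlt_learning",          42,          9,    22,     8,     28,      8,     24,      8,
    "ravlt_recall",             9,          3,     2,     2,      4,      3,      4,      3,
    "tmt_a",                   37,         20,    79,    54,     57,     36,     96,     57,
    "tmt_b",                   85,         39,   193,    80,    155,     77,    220,     86,
    "animal_fluency",          22,          5,    13,     5,     12,      7,     11,      4,
    "npi_total",                7,          9,    11,    11,     22,     17,     16,     10,
    "cmta_right",             0.3,        0.5,   1.4,   0.8,    1.6,    1.2,    1.5,    1.0,
    "cmta_left",              0.3,        0.5,   1.5,   0.9,    2.0,    1.4,    1.5,    1.2,
    "cgca",                   0.3,        0.5,   1.2,   0.8,    1.3,    0.8,    1.4,    0.7,
    "wmh_ml",                 2.9,        4.7,   6.6,   9.9,    3.6,    7.7,   44.5,   29.6,
    "ad_similarity",          0.4,        0.1,   0.6,   0.1,    0.4,    0.1,    0.6,    0.1,
    "ap_index",               0.1,        0.7,   0.1,   1.2,   -2.1,    1.7,    0.1,    1.1,
    "ab42",                   928,        280,   535,   183,    914,    250,    704,    252,
    "total_tau",              322,        208,   693,   405,    337,    140,    308,    162,
    "p_tau",                   52,         24,    86,    39,     45,     18,     43,     18
  )
  feature_params <- tidyr::pivot_longer(
    fp, -"feature",
    names_to = c("group", ".value"), names_sep = "_"
  )
  names(feature_params)[names(feature_params) == "m"] <- "mean"
  names(feature_params)[names(feature_params) == "s"] <- "sd"

  structure(
    list(
      group_sizes = c(CONTROL = 139L, AD = 286L, FTD = 82L, VAD = 28L),
      age = tibble::tibble(
        group = diagnosis_levels(),
        mean = c(62, 67, 63, 70), sd = c(8, 8, 6, 8)
      ),
      sex_female = c(CONTROL = 0.43, AD = 0.55, FTD = 0.44, VAD = 0.29),
      apoe_freq = c(CONTROL = 0.42, AD = 0.65, FTD = 0.34, VAD = 0.48),
      feature_params = feature_params,
      missing_rates = c(
        apoe_e4 = 0.12, mmse = 0.01, ravlt_learning = 0.05,
        ravlt_recall = 0.05, tmt_a = 0.04, tmt_b = 0.24,
        animal_fluency = 0.03, npi_total = 0.17,
        cmta_right = 0, cmta_left = 0, cgca = 0, wmh_ml = 0,
        ad_similarity = 0, ap_index = 0,
        ab42 = 0, total_tau = 0, p_tau = 0
      ),
      correlation = 0.3,
      separation_scale = 1,
      age_loading = 0.3,
      seed = 1L
    ),
    class = "generator_config"
  )
}

# Clinical direction of aging per feature (sign of the age loading in
# the copula): cognition and AB42 decline, atrophy/lesions/tau rise.
age_slope_signs <- function() c(
  mmse = -1, ravlt_learning = -1, ravlt_recall = -1, tmt_a = 1, tmt_b = 1,
  animal_fluency = -1, npi_total = 1, cmta_right = 1, cmta_left = 1,
  cgca = 1, wmh_ml = 1, ad_similarity = 1, ap_index = -1,
  ab42 = -1, total_tau = 1, p_tau = 1
)

# Moment-matched Beta parameters on [lower, upper].  Means are pulled
# just inside the range when needed to keep the configured SD feasible
# (relevant at high separation_scale); a mean that would have to move
# by more than 20% of the range is an error.
beta_match <- function(m, s, lower, upper, feature, group) {
  range <- upper - lower
  # SDs above the Beta feasibility limit for the bounded range (can
  # occur at exaggerated separation scales) are capped at it
  v <- min((s / range)^2, 0.95 / 4.4)
  disc <- 1 - 4 * 1.1 * v
  mu_lo <- (1 - sqrt(disc)) / 2
  mu_hi <- (1 + sqrt(disc)) / 2
  mu <- min(max((m - lower) / range, mu_lo), mu_hi)
  if (abs(mu - (m - lower) / range) > 0.2) {
    stop(sprintf(
      "infeasible truncation for '%s' (%s): mean %g far outside plausible range [%g, %g]",
      feature, group, m, lower, upper
    ), call. = FALSE)
  }
  vmax <- mu * (1 - mu)
  if (v >= vmax) v <- 0.95 * vmax
  nu <- vmax / v - 1
  list(shape1 = mu * nu, shape2 = (1 - mu) * nu,
       lower = lower, range = range)
}

# Truncated normal draw that also returns the underlying standard
# normal rank (used as the age factor of the feature copula).
rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n)
  list(value = stats::qnorm(plo + u * (phi - plo), mean, sd),
       z = stats::qnorm(u))
}

#' Generate a synthetic four-group memory-clinic cohort
#'
#' Draws a labeled cohort from the configuration: age from a normal
#' distribution truncated to \[40, 95\]; sex and APOE carrier status
#' Bernoulli; continuous features through a Gaussian copula with
#' scaled-Beta marginals on each feature's plausible range,
#' moment-matched to the configured group mean and SD.  The copula has
#' two factors: a within-modality common factor (equicorrelation
#' `correlation`) and the latent normal rank of age, loaded with weight
#' `age_loading` and a fixed clinical sign per feature — so every
#' feature carries a monotone age effect for the age/sex correction to
#' remove, while group means and SDs still match the configuration
#' exactly.  Missingness is applied completely at random at the
#' configured per-feature rates; CSF is never missing.  The result is
#' deterministic given `config$seed`.
#'
#' @param config A `generator_config`, see [default_generator_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A labeled, uncorrected cohort tibble.
#' @export
generate_cohort <- function(config = default_generator_config(),
                            seed = NULL) {
  seed <- if (is.null(seed)) config$seed else seed
  withr::local_seed(as.integer(seed))

  groups <- diagnosis_levels()
  sizes <- config$group_sizes[groups]
  stopifnot(all(sizes >= 1))
  s <- config$separation_scale
  stopifnot(s >= 0)
  w <- sizes / sum(sizes)

  cat <- feature_catalog()
  fp <- config$feature_params
  features <- unique(fp$feature)
  signs <- age_slope_signs()

  # pooled (size-weighted) parameters; separation interpolates toward them
  pooled <- fp |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(
      mean = sum(.data$mean * w[.data$group]),
      sd = sum(.data$sd * w[.data$group]), .groups = "drop"
    )
  blend <- function(g_val, pool_val) pool_val + s * (g_val - pool_val)

  age_pool_mean <- sum(config$age$mean * w[config$age$group])
  age_pool_sd <- sum(config$age$sd * w[config$age$group])
  a_load <- config$age_loading
  stopifnot(a_load >= 0, a_load^2 < 1)

  out <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    n <- sizes[[g]]
    age_m <- blend(config$age$mean[config$age$group == g], age_pool_mean)
    age_s <- blend(config$age$sd[config$age$group == g], age_pool_sd)
    p_f <- blend(config$sex_female[[g]], sum(config$sex_female * w))
    p_e4 <- blend(config$apoe_freq[[g]], sum(config$apoe_freq * w))

    age_draw <- rtruncnorm1(n, age_m, age_s, 40, 95)
    age <- age_draw$value
    sex <- ifelse(stats::runif(n) < p_f, "F", "M")
    apoe <- as.double(stats::runif(n) < p_e4)

    # copula: age factor (signed loading) + within-modality common
    # factor + idiosyncratic noise, all on the latent normal scale
    z <- matrix(NA_real_, n, length(features),
                dimnames = list(NULL, features))
    for (mod in unique(cat$modality[cat$name %in% features])) {
      fs <- intersect(features, cat$name[cat$modality == mod &
                                           cat$kind == "continuous"])
      if (length(fs) == 0) next
      b2 <- max(config$correlation - a_load^2, 0)
      e2 <- 1 - a_load^2 - b2
      common <- stats::rnorm(n)
      for (f in fs) {
        z[, f] <- signs[[f]] * a_load * age_draw$z +
          sqrt(b2) * common + sqrt(e2) * stats::rnorm(n)
      }
    }

    vals <- list()
    for (f in features) {
      row <- fp[fp$feature == f & fp$group == g, ]
      prow <- pooled[pooled$feature == f, ]
      m <- blend(row$mean, prow$mean)
      sdv <- blend(row$sd, prow$sd)
      spec <- cat[cat$name == f, ]
      bm <- beta_match(m, sdv, spec$lower, spec$upper, f, g)
      # qbeta warns about tail precision for very skewed shapes; the
      # residual inaccuracy is orders of magnitude below feature SDs
      q <- suppressWarnings(stats::qbeta(stats::pnorm(z[, f]),
                                         bm$shape1, bm$shape2))
      vals[[f]] <- pmin(pmax(bm$lower + bm$range * q, spec$lower),
                        spec$upper)
    }

    out[[gi]] <- tibble::tibble(
      patient_id = sprintf("%s%04d", substr(g, 1, 1), seq_len(n)),
      age = age, sex = sex, diagnosis = g, apoe_e4 = apoe,
      !!!vals
    )
  }
  df <- dplyr::bind_rows(out)
  df$patient_id <- sprintf("S%04d", seq_len(nrow(df)))

  # missingness, completely at random
  for (f in names(config$missing_rates)) {
    r <- config$missing_rates[[f]]
    if (r > 0 && f %in% names(df)) {
      df[[f]][stats::runif(nrow(df)) < r] <- NA_real_
    }
  }
  df <- df[, c(id_columns(), intersect(cat$name, names(df)))]
  as_cohort(df)
}

#' Read / write a generator configuration as YAML
#'
#' @param path A YAML file path.
#' @return `read_generator_config()`: a `generator_config`;
#'   `write_generator_config()`: `path` invisibly.
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_generator_config()
  for (nm in intersect(names(raw), c("correlation", "separation_scale",
                                     "age_loading", "seed"))) {
    cfg[[nm]] <- raw[[nm]]
  }
  if (!is.null(raw$group_sizes)) {
    gs <- unlist(raw$group_sizes)
    cfg$group_sizes[names(gs)] <- as.integer(gs)
  }
  if (!is.null(raw$missing_rates)) {
    mr <- unlist(raw$missing_rates)
    cfg$missing_rates[names(mr)] <- mr
  }
  if (!is.null(raw$sex_female)) {
    v <- unlist(raw$sex_female)
    cfg$sex_female[names(v)] <- v
  }
  if (!is.null(raw$apoe_freq)) {
    v <- unlist(raw$apoe_freq)
    cfg$apoe_freq[names(v)] <- v
  }
  if (!is.null(raw$feature_params)) {
    for (fp in raw$feature_params) {
      sel <- cfg$feature_params$feature == fp$feature &
        cfg$feature_params$group == fp$group
      if (!any(sel)) stop("unknown feature/group in config: ",
                          fp$feature, "/", fp$group, call. = FALSE)
      cfg$feature_params$mean[sel] <- fp$mean
      cfg$feature_params$sd[sel] <- fp$sd
    }
  }
  cfg
}

#' @param config A `generator_config`.
#' @rdname read_generator_config
#' @export
write_generator_config <- function(config, path) {
  out <- list(
    group_sizes = as.list(config$group_sizes),
    sex_female = as.list(config$sex_female),
    apoe_freq = as.list(config$apoe_freq),
    missing_rates = as.list(config$missing_rates),
    correlation = config$correlation,
    separation_scale = config$separation_scale,
    age_loading = config$age_loading,
    seed = config$seed,
    feature_params = purrr::pmap(config$feature_params,
                                 function(feature, group, mean, sd) {
                                   list(feature = feature, group = group,
                                        mean = mean, sd = sd)
                                 })
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
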