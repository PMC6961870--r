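#' Fit a fitness function for one feature and group pair
#'
#' The Disease State Index evaluates each test result through a
#' nonparametric fitness function built from a labeled reference set.
#' Using the patient's value `x` as a classification cutoff between the
#' positive and negative group, the fitness is
#' `f(x) = FN(x) / (FN(x) + FP(x))` where `FN` is the false-negative
#' rate (share of positive-group reference values below the cutoff) and
#' `FP` the false-positive rate (share of negative-group values at or
#' above it).  `f` maps a raw measurement to evidence in `[0, 1]` toward
#' the positive group: 0 below the pooled reference minimum, 1 above the
#' pooled maximum, and weakly monotone in between.  Across a separation
#' gap where `FN + FP = 0`, `f` is linearly interpolated in `x`.
#'
#' The direction of the comparison (whether high or low raw values point
#' to the positive group) is chosen per feature and pair as the
#' orientation that maximizes Youden's J on the reference data, ties
#' broken toward higher-is-positive.  When all reference values are
#' identical across both groups the function is degenerate and returns a
#' constant 0.5 (with `degenerate = TRUE`); its relevance is 0, so it
#' never influences a DSI.
#'
#' @param pos_values,neg_values Covariate-corrected reference values of
#'   the positive and negative group; `NA`s are dropped.
#' @return An object of class `fitness_function` with fields `pos`,
#'   `neg` (sorted reference values), `orientation` (+1 high-is-positive,
#'   -1 low-is-positive), `relevance` (max Youden's J) and `degenerate`.
#' @examples
#' ff <- fit_fitness_function(c(1, 3, 5), c(0, 2, 4))
#' evaluate_fitness(ff, 2.5)  # FN = 1/3, FP = 1/3 -> 0.5
#' @export
fit_fitness_function <- function(pos_values, neg_values) {
  pos <- sort(pos_values[!is.na(pos_values)])
  neg <- sort(neg_values[!is.na(neg_values)])
  if (length(pos) == 0 || length(neg) == 0) {
    stop("both groups need at least one observed reference value",
         call. = FALSE)
  }
  ff <- ff_fit_core(pos, neg)
  if (ff$degenerate) {
    warning("all reference values identical across both groups; ",
            "degenerate fitness function f = 0.5", call. = FALSE)
  }
  ff
}

# Core fit on pre-sorted, NA-free vectors (hot path of leave-one-out).
ff_fit_core <- function(pos, neg) {
  v <- sort.int(unique.default(c(pos, neg)), method = "quick")
  np <- length(pos)
  nq <- length(neg)
  if (length(v) == 1L) {
    out <- list(pos = pos, neg = neg, orientation = 1L, relevance = 0,
                degenerate = TRUE)
    class(out) <- "fitness_function"
    return(out)
  }
  p_lt <- findInterval(v, pos, left.open = TRUE)
  q_lt <- findInterval(v, neg, left.open = TRUE)
  p_le <- findInterval(v, pos)
  q_le <- findInterval(v, neg)
  # rule ">= c => positive": J = spec + sens - 1 = #neg<c/nq - #pos<c/np
  j_high <- max(q_lt / nq - p_lt / np, 0)
  # rule "<= c => positive": J = #pos<=c/np - #neg<=c/nq
  j_low <- max(p_le / np - q_le / nq, 0)
  orientation <- if (j_high >= j_low) 1L else -1L
  out <- list(pos = pos, neg = neg, orientation = orientation,
              relevance = max(j_high, j_low), degenerate = FALSE)
  class(out) <- "fitness_function"
  out
}

#' Evaluate a fitness function
#'
#' @param ff A `fitness_function` from [fit_fitness_function()].
#' @param x Numeric vector of query values (the patient's measurement).
#' @return Numeric vector of fitness values in `[0, 1]`; `NA` in gives
#'   `NA` out.
#' @export
evaluate_fitness <- function(ff, x) {
  out <- rep(NA_real_, length(x))
  ok <- which(!is.na(x))
  if (length(ok) == 0) return(out)
  out[ok] <- ff_eval_core(ff, x[ok])
  out
}

# x must be NA-free.
ff_eval_core <- function(ff, x) {
  if (ff$degenerate) return(rep(0.5, length(x)))
  pos <- ff$pos
  neg <- ff$neg
  np <- length(pos)
  nq <- length(neg)
  if (ff$orientation > 0) {
    fn <- findInterval(x, pos, left.open = TRUE) / np     # share pos < x
    fp <- (nq - findInterval(x, neg, left.open = TRUE)) / nq  # share neg >= x
  } else {
    fn <- (np - findInterval(x, pos)) / np                # share pos > x
    fp <- findInterval(x, neg) / nq                       # share neg <= x
  }
  tot <- fn + fp
  f <- ifelse(tot > 0, fn / tot, NA_real_)
  gap <- which(is.na(f))
  if (length(gap) > 0) {
    # FN = FP = 0: x lies in the separation gap between the groups;
    # interpolate linearly from 0 at the gap's negative edge to 1 at its
    # positive edge.
    if (ff$orientation > 0) {
      a <- neg[nq]
      b <- pos[1]
      f[gap] <- (x[gap] - a) / (b - a)
    } else {
      a <- neg[1]
      b <- pos[np]
      f[gap] <- (a - x[gap]) / (a - b)
    }
  }
  pmin(pmax(f, 0), 1)
}

#' Relevance (maximum Youden's J) of a feature for a group pair
#'
#' The weight a feature carries in the Disease State Index for one
#' pairwise comparison: sensitivity + specificity - 1 on the reference
#' data, maximized over all candidate cutoffs and over the two possible
#' orientations.  A feature that cannot discriminate the pair at any
#' cutoff has relevance 0 and contributes nothing.
#'
#' @inheritParams fit_fitness_function
#' @return A number in `[0, 1]`.
#' @examples
#' compute_relevance(c(1, 3, 5), c(0, 2, 4))  # 1/3
#' compute_relevance(c(2, 3), c(0, 1))        # perfect separation: 1
#' @export
compute_relevance <- function(pos_values, neg_values) {
  pos <- sort(pos_values[!is.na(pos_values)])
  neg <- sort(neg_values[!is.na(neg_values)])
  if (length(pos) == 0 || length(neg) == 0) {
    stop("both groups need at least one observed reference value",
         call. = FALSE)
  }
  ff_fit_core(pos, neg)$relevance
}

#' Fit a Disease State Index model
#'
#' Fits, for every canonical group pair (see [canonical_pairs()]) and
#' every feature of `features`, a fitness function and a relevance
#' weight from the labeled, covariate-corrected reference cohort.  A
#' feature enters a pair only when both groups have at least `min_ref`
#' observed values for it; features with insufficient data are absent
#' for that pair only.  Reversed pairs are derived by the complement
#' `1 - DSI` and are not refitted.
#'
#' @param reference A corrected, labeled cohort containing all four
#'   diagnostic groups.
#' @param features Character vector of feature names (default: all
#'   non-CSF features, see [feature_subset()]).
#' @param min_ref Minimum observations per group per feature (default 5).
#' @return An object of class `dsi_model`.
#' @export
fit_dsi <- function(reference, features = feature_subset("nocsf"),
                    min_ref = 5) {
  stopifnot_corrected(reference, "fit_dsi()")
  features <- intersect(features, cohort_features(reference))
  groups <- diagnosis_levels()
  labels <- reference$diagnosis
  sizes <- vapply(groups, function(g) sum(!is.na(labels) & labels == g),
                  integer(1))
  absent <- groups[sizes < min_ref]
  if (length(absent) > 0) {
    stop("reference group(s) with fewer than min_ref = ", min_ref,
         " members: ", paste(absent, collapse = ", "), call. = FALSE)
  }

  group_values <- lapply(groups, function(g) {
    rows <- which(!is.na(labels) & labels == g)
    lapply(stats::setNames(features, features), function(f) {
      sort(reference[[f]][rows][!is.na(reference[[f]][rows])])
    })
  })
  names(group_values) <- groups

  pairs <- canonical_pairs()
  pair_fits <- purrr::pmap(pairs, function(positive, negative) {
    fits <- list()
    for (f in features) {
      pos <- group_values[[positive]][[f]]
      neg <- group_values[[negative]][[f]]
      if (length(pos) >= min_ref && length(neg) >= min_ref) {
        fits[[f]] <- ff_fit_core(pos, neg)
      }
    }
    fits
  })
  names(pair_fits) <- paste(pairs$positive, pairs$negative, sep = "_vs_")

  structure(
    list(pairs = pair_fits, features = features, min_ref = min_ref,
         group_sizes = sizes),
    class = "dsi_model"
  )
}

#' @export
print.dsi_model <- function(x, ...) {
  cat("Disease State Index model\n")
  cat("  features:", length(x$features), "-",
      paste(utils::head(x$features, 6), collapse = ", "),
      if (length(x$features) > 6) "..." else "", "\n")
  cat("  reference group sizes:",
      paste(names(x$group_sizes), x$group_sizes, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

# Pairwise DSI for one record's named value vector against one fitted
# pair: relevance-weighted mean of fitness values over the features that
# are both observed and present for this pair.  Returns list(dsi, n).
# dsi is NA when no feature is usable, 0.5 when usable features all have
# zero relevance (uninformative evidence is neutral).
pair_dsi_values <- function(fits, values) {
  num <- 0
  den <- 0
  n <- 0L
  for (f in names(fits)) {
    x <- values[[f]]
    if (is.null(x) || is.na(x)) next
    ff <- fits[[f]]
    n <- n + 1L
    w <- ff$relevance
    if (w <= 0) next
    num <- num + w * ff_eval_core(ff, x)
    den <- den + w
  }
  if (n == 0L) return(list(dsi = NA_real_, n = 0L))
  list(dsi = if (den > 0) num / den else 0.5, n = n)
}

# Full per-record evaluation used by classify/PCC/scenarios.
# values: named list/vector of feature values (NA = missing).
# Returns list(pairwise, totals, predicted, d1, d2, margin, tie, n_features).
dsi_eval_record <- function(model, values) {
  pairs <- canonical_pairs()
  keys <- names(model$pairs)
  pw <- numeric(nrow(pairs))
  npw <- integer(nrow(pairs))
  used <- character(0)
  for (i in seq_len(nrow(pairs))) {
    res <- pair_dsi_values(model$pairs[[keys[i]]], values)
    pw[i] <- res$dsi
    npw[i] <- res$n
    if (res$n > 0) used <- union(used, names(model$pairs[[keys[i]]]))
  }
  groups <- diagnosis_levels()
  totals <- stats::setNames(numeric(4), groups)
  for (g in groups) {
    vals <- numeric(0)
    for (i in seq_len(nrow(pairs))) {
      if (is.na(pw[i])) next
      if (pairs$positive[i] == g) vals <- c(vals, pw[i])
      else if (pairs$negative[i] == g) vals <- c(vals, 1 - pw[i])
    }
    if (length(vals) == 0) {
      obs <- names(values)[!vapply(values, function(v) is.null(v) || is.na(v),
                                   logical(1))]
      stop("no pairwise DSI defined for group ", g,
           "; observed features usable by the model: ",
           paste(intersect(obs, model$features), collapse = ", "),
           call. = FALSE)
    }
    totals[g] <- mean(vals)
  }
  ord <- order(-totals, match(groups, diagnosis_levels()))
  d1 <- totals[ord[1]]
  d2 <- totals[ord[2]]
  tie <- sum(abs(totals - d1) < 1e-12) > 1
  predicted <- groups[totals == max(totals)][1]  # fixed-order tie-break
  list(pairwise = stats::setNames(pw, keys),
       n_pair_features = stats::setNames(npw, keys),
       totals = totals, predicted = predicted,
       d1 = unname(d1), d2 = unname(d2), margin = unname(d1 - d2),
       tie = tie, n_features = length(used))
}

record_values <- function(cohort, row, features) {
  vals <- lapply(features, function(f) {
    if (f %in% names(cohort)) cohort[[f]][row] else NA_real_
  })
  names(vals) <- features
  vals
}

#' Classify a cohort with a fitted DSI model
#'
#' Computes, for every patient, the total Disease State Index of each
#' diagnostic group (the unweighted mean of that group's three pairwise
#' DSIs, with reversed pairs obtained by complement), the predicted
#' class (argmax, ties broken by the fixed order CONTROL < AD < FTD <
#' VAD and flagged), the top value `d1`, runner-up `d2` and the margin
#' `delta = d1 - d2`.  Only observed features are used; a patient
#' missing every usable feature for some group is an error.
#'
#' @param cohort A covariate-corrected cohort.
#' @param model A `dsi_model` from [fit_dsi()].
#' @return A tibble with one row per patient: `patient_id`,
#'   `dsi_CONTROL`, `dsi_AD`, `dsi_FTD`, `dsi_VAD`, `predicted`, `d1`,
#'   `d2`, `margin`, `tie`, `n_features_used`.
#' @export
dsi_classify <- function(cohort, model) {
  stopifnot_corrected(cohort, "dsi_classify()")
  groups <- diagnosis_levels()
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    ev <- dsi_eval_record(model, record_values(cohort, i, model$features))
    tibble::tibble(
      patient_id = cohort$patient_id[i],
      dsi_CONTROL = ev$totals[["CONTROL"]], dsi_AD = ev$totals[["AD"]],
      dsi_FTD = ev$totals[["FTD"]], dsi_VAD = ev$totals[["VAD"]],
      predicted = ev$predicted, d1 = ev$d1, d2 = ev$d2, margin = ev$margin,
      tie = ev$tie, n_features_used = ev$n_features
    )
  })
  dplyr::bind_rows(rows)
}

#' Pairwise DSI values for a cohort
#'
#' The six canonical pairwise comparisons per patient, in long form.
#' The reversed comparison is `1 -` the stored value.
#'
#' @inheritParams dsi_classify
#' @return A tibble `patient_id`, `positive`, `negative`, `dsi`,
#'   `n_features` (NA `dsi` when no usable feature is observed).
#' @export
dsi_pairwise <- function(cohort, model) {
  stopifnot_corrected(cohort, "dsi_pairwise()")
  pairs <- canonical_pairs()
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    keys <- names(model$pairs)
    res <- purrr::map(keys, function(k) pair_dsi_values(model$pairs[[k]],
                                                        record_values(cohort, i, model$features)))
    tibble::tibble(
      patient_id = cohort$patient_id[i],
      positive = pairs$positive, negative = pairs$negative,
      dsi = vapply(res, `[[`, numeric(1), "dsi"),
      n_features = vapply(res, `[[`, integer(1), "n")
    )
  })
  dplyr::bind_rows(rows)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a DSI model into its relevance weights
#'
#' @param x A `dsi_model`.
#' @param ... Unused.
#' @return A tibble with one row per (pair, feature): `positive`,
#'   `negative`, `feature`, `relevance`, `orientation`, `n_pos`,
#'   `n_neg`, `degenerate`.
#' @method tidy dsi_model
#' @export
tidy.dsi_model <- function(x, ...) {
  pairs <- canonical_pairs()
  keys <- names(x$pairs)
  purrr::map_dfr(seq_along(keys), function(i) {
    fits <- x$pairs[[keys[i]]]
    if (length(fits) == 0) return(tibble::tibble())
    tibble::tibble(
      positive = pairs$positive[i], negative = pairs$negative[i],
      feature = names(fits),
      relevance = vapply(fits, `[[`, numeric(1), "relevance"),
      orientation = vapply(fits, `[[`, integer(1), "orientation"),
      n_pos = vapply(fits, function(f) length(f$pos), integer(1)),
      n_neg = vapply(fits, function(f) length(f$neg), integer(1)),
      degenerate = vapply(fits, `[[`, logical(1), "degenerate")
    )
  })
}

#' @rdname tidy.dsi_model
#' @method glance dsi_model
#' @export
glance.dsi_model <- function(x, ...) {
  tibble::tibble(
    n_pairs = length(x$pairs),
    n_features = length(x$features),
    min_ref = x$min_ref,
    n_reference = sum(x$group_sizes)
  )
}
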