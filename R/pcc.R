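#' Build a probability-of-correct-class (PCC) model
#'
#' PCC turns the classifier's output for one patient — the top total
#' DSI `d1` and the margin `delta = d1 - d2` to the runner-up group —
#' into a personalized confidence: the share of correctly classified
#' reference cases whose `(d1, delta)` lie close to the patient's.  A
#' patient with top DSI 0.75 and second DSI 0.67 is therefore compared
#' with reference cases with DSI close to 0.75 and margin close to
#' 0.08.
#'
#' Reference points are built honestly by leave-one-out: each reference
#' case is classified under a model refitted without it, and the point
#' records its `(d1, delta)` together with whether the predicted class
#' matched the clinical label.  "Close to" is operationalized as the
#' `k` nearest reference points in Euclidean distance on z-standardized
#' `(d1, delta)`, with ties at the k-th distance included.  One PCC
#' model belongs to one feature subset: confidence before and after
#' adding CSF biomarkers lives in different reference geometries.
#'
#' @param reference A corrected, labeled cohort; every group needs at
#'   least `min_ref + 1` members so leave-one-out refits stay valid.
#' @param features Feature subset (default: no-CSF subset).
#' @param k Neighborhood size; default `max(20, ceiling(0.1 * N))`
#'   where `N` is the number of reference points (minimum 5).
#' @param min_ref Passed to [fit_dsi()].
#' @return An object of class `pcc_model` with fields `points` (tibble
#'   `patient_id`, `d1`, `delta`, `predicted`, `diagnosis`, `correct`),
#'   `k`, `standardization` and `features`.
#' @export
fit_pcc <- function(reference, features = feature_subset("nocsf"),
                    k = NULL, min_ref = 5) {
  stopifnot_corrected(reference, "fit_pcc()")
  labels <- reference$diagnosis
  if (anyNA(labels)) {
    stop("PCC reference cohort must be fully labeled", call. = FALSE)
  }
  sizes <- table(factor(labels, diagnosis_levels()))
  small <- names(sizes)[sizes < min_ref + 1]
  if (length(small) > 0) {
    stop("group(s) too small for leave-one-out refits (need >= ",
         min_ref + 1, "): ", paste(small, collapse = ", "), call. = FALSE)
  }

  points <- loo_reference_points(reference, features, min_ref)
  n <- nrow(points)
  if (is.null(k)) k <- max(20L, ceiling(0.1 * n))
  k <- max(5L, as.integer(k))
  sd_or_1 <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) 1 else s
  }
  structure(
    list(points = points, k = min(k, n),
         standardization = list(d1_mean = mean(points$d1),
                                d1_sd = sd_or_1(points$d1),
                                delta_mean = mean(points$delta),
                                delta_sd = sd_or_1(points$delta)),
         features = features, min_ref = min_ref),
    class = "pcc_model"
  )
}

# Leave-one-out (d1, delta, correct) points.  For the left-out case
# only the three pairs involving its own group change, and within those
# only the features it has observed; everything else reuses the full
# fit.  Dropping a value from an already-sorted reference vector keeps
# the refit O(n).
loo_reference_points <- function(reference, features, min_ref) {
  full <- fit_dsi(reference, features, min_ref)
  features <- full$features
  pairs <- canonical_pairs()
  keys <- names(full$pairs)
  labels <- reference$diagnosis
  groups <- diagnosis_levels()

  # raw per-group sorted values incl. those below min_ref (a refit can
  # only shrink counts, so pairs absent from the full fit stay absent)
  group_rows <- lapply(stats::setNames(groups, groups),
                       function(g) which(labels == g))

  n <- nrow(reference)
  d1 <- numeric(n)
  delta <- numeric(n)
  predicted <- character(n)

  for (i in seq_len(n)) {
    g <- labels[i]
    vals <- record_values(reference, i, features)
    model_i <- full
    for (p in seq_along(keys)) {
      if (pairs$positive[p] != g && pairs$negative[p] != g) next
      side <- if (pairs$positive[p] == g) "pos" else "neg"
      fits <- full$pairs[[keys[p]]]
      for (f in names(fits)) {
        x <- vals[[f]]
        if (is.na(x)) next
        ref_vals <- fits[[f]][[side]]
        idx <- findInterval(x, ref_vals)
        dropped <- ref_vals[-idx]
        if (length(dropped) < min_ref) {
          model_i$pairs[[keys[p]]][[f]] <- NULL
        } else if (side == "pos") {
          model_i$pairs[[keys[p]]][[f]] <- ff_fit_core(dropped, fits[[f]]$neg)
        } else {
          model_i$pairs[[keys[p]]][[f]] <- ff_fit_core(fits[[f]]$pos, dropped)
        }
      }
    }
    ev <- dsi_eval_record(model_i, vals)
    d1[i] <- ev$d1
    delta[i] <- ev$margin
    predicted[i] <- ev$predicted
  }

  tibble::tibble(
    patient_id = reference$patient_id,
    d1 = d1, delta = delta, predicted = predicted,
    diagnosis = labels, correct = predicted == labels
  )
}

#' Estimate the probability of correct class for query coordinates
#'
#' @param model A `pcc_model` from [fit_pcc()].
#' @param d1 Top total DSI value(s) in `[0, 1]`.
#' @param delta Margin(s) `d1 - d2`, with `0 <= delta <= d1`.
#' @return A tibble with one row per query: `d1`, `delta`, `value`
#'   (share of correct neighbors, in `[0, 1]`) and `n_neighbors`
#'   (`>= k` when ties are included).
#' @examples
#' \dontrun{
#' estimate_pcc(model, d1 = 0.75, delta = 0.75 - 0.67)
#' }
#' @export
estimate_pcc <- function(model, d1, delta) {
  if (length(d1) != length(delta)) {
    stop("d1 and delta must have the same length", call. = FALSE)
  }
  bad <- which(is.na(d1) | is.na(delta) | d1 < 0 | d1 > 1 |
                 delta < 0 | delta > d1 + 1e-12)
  if (length(bad) > 0) {
    stop(sprintf(
      "query outside bounds 0 <= delta <= d1 <= 1 (query %d: d1 = %s, delta = %s)",
      bad[1], format(d1[bad[1]]), format(delta[bad[1]])
    ), call. = FALSE)
  }
  st <- model$standardization
  pz1 <- (model$points$d1 - st$d1_mean) / st$d1_sd
  pz2 <- (model$points$delta - st$delta_mean) / st$delta_sd
  qz1 <- (d1 - st$d1_mean) / st$d1_sd
  qz2 <- (delta - st$delta_mean) / st$delta_sd
  correct <- model$points$correct
  k <- model$k

  value <- numeric(length(d1))
  n_nb <- integer(length(d1))
  for (i in seq_along(d1)) {
    dist2 <- (pz1 - qz1[i])^2 + (pz2 - qz2[i])^2
    kth <- sort.int(dist2, partial = k)[k]
    sel <- dist2 <= kth + 1e-12  # ties at the k-th distance included
    value[i] <- mean(correct[sel])
    n_nb[i] <- sum(sel)
  }
  tibble::tibble(d1 = d1, delta = delta, value = value, n_neighbors = n_nb)
}

#' PCC calibration against empirical accuracy
#'
#' Checks the claim that PCC estimates per-patient classification
#' accuracy: evaluation patients are binned by estimated PCC (equal
#' width bins on `[0, 1]`) and each bin's mean PCC is compared with the
#' share of correct predictions inside it.
#'
#' @param model A `pcc_model`.
#' @param eval A corrected, labeled cohort, ideally disjoint from the
#'   model's reference (overlap is allowed but flagged with a warning,
#'   since it makes the empirical accuracy optimistic).
#' @param dsi A `dsi_model` fitted on the same feature subset.
#' @param bins Number of equal-width PCC bins (default 10).
#' @return A tibble of class `pcc_calibration`: `bin`, `bin_low`,
#'   `bin_high`, `n`, `mean_pcc`, `accuracy` (empty bins have `n = 0`
#'   and `NA` statistics).
#' @export
pcc_calibration <- function(model, eval, dsi, bins = 10) {
  stopifnot_corrected(eval, "pcc_calibration()")
  if (anyNA(eval$diagnosis)) {
    stop("calibration requires a labeled evaluation cohort", call. = FALSE)
  }
  if (any(eval$patient_id %in% model$points$patient_id)) {
    warning("evaluation cohort overlaps the PCC reference; ",
            "empirical accuracy will be optimistic", call. = FALSE)
  }
  cls <- dsi_classify(eval, dsi)
  est <- estimate_pcc(model, cls$d1, cls$margin)
  correct <- cls$predicted == eval$diagnosis

  breaks <- seq(0, 1, length.out = bins + 1)
  idx <- pmin(pmax(findInterval(est$value, breaks, rightmost.closed = TRUE),
                   1L), bins)
  out <- purrr::map_dfr(seq_len(bins), function(b) {
    sel <- idx == b
    tibble::tibble(
      bin = b, bin_low = breaks[b], bin_high = breaks[b + 1],
      n = sum(sel),
      mean_pcc = if (any(sel)) mean(est$value[sel]) else NA_real_,
      accuracy = if (any(sel)) mean(correct[sel]) else NA_real_
    )
  })
  class(out) <- c("pcc_calibration", class(out))
  out
}

#' @export
print.pcc_model <- function(x, ...) {
  cat("PCC model:", nrow(x$points), "leave-one-out reference points, k =",
      x$k, "\n")
  cat("  leave-one-out accuracy:",
      sprintf("%.3f", mean(x$points$correct)), "\n")
  invisible(x)
}

#' Tidy / glance methods for PCC models
#'
#' @param x A `pcc_model`.
#' @param ... Unused.
#' @return `tidy()`: the reference points tibble; `glance()`: a one-row
#'   tibble with `n_points`, `k` and `loo_accuracy`.
#' @method tidy pcc_model
#' @export
tidy.pcc_model <- function(x, ...) x$points

#' @rdname tidy.pcc_model
#' @method glance pcc_model
#' @export
glance.pcc_model <- function(x, ...) {
  tibble::tibble(n_points = nrow(x$points), k = x$k,
                 loo_accuracy = mean(x$points$correct))
}
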