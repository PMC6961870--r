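#' Plot a PCC cutoff sweep
#'
#' Shares of patients diagnosed and of patients with CSF tested as a
#' function of the PCC cutoff, one panel per quantity, one line per
#' scenario.
#'
#' @param object A `triage_sweep` tibble from [sweep_pcc_cutoffs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot triage_sweep
#' @export
autoplot.triage_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object, c("share_diagnosed", "share_tested"),
    names_to = "quantity", values_to = "share"
  )
  long$quantity <- dplyr::recode(long$quantity,
                                 share_diagnosed = "Diagnosed (PCC >= cutoff)",
                                 share_tested = "CSF tested")
  ggplot2::ggplot(long, ggplot2::aes(.data$cutoff, .data$share,
                                     colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~quantity) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "PCC cutoff", y = "Share of patients",
                  colour = "Scenario") +
    ggplot2::theme_minimal()
}

#' Plot PCC calibration
#'
#' Mean estimated PCC versus empirical accuracy per calibration bin;
#' points on the diagonal indicate a well-calibrated confidence.
#'
#' @param object A `pcc_calibration` tibble from [pcc_calibration()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pcc_calibration
#' @export
autoplot.pcc_calibration <- function(object, ...) {
  dat <- object[object$n > 0, ]
  ggplot2::ggplot(dat, ggplot2::aes(.data$mean_pcc, .data$accuracy,
                                    size = .data$n)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Mean estimated PCC (bin)",
                  y = "Empirical accuracy (bin)", size = "n") +
    ggplot2::theme_minimal()
}

#' Plot the PCC reference geometry
#'
#' The leave-one-out reference points in the (top DSI, margin) plane,
#' coloured by whether the left-out case was classified correctly.
#'
#' @param object A `pcc_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pcc_model
#' @export
autoplot.pcc_model <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(.data$d1, .data$delta,
                               colour = .data$correct)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(x = "Top total DSI (d1)", y = "Margin (d1 - d2)",
                  colour = "Correct") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
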