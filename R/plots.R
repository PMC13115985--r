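#' Plot an accuracy curve
#'
#' Solid lines are the local-likelihood estimates over the VAS range;
#' dashed lines bound the 95% bootstrap bands (when fitted with `B > 0`).
#' Panels split sensitivity and specificity; colour distinguishes tests.
#'
#' @param object A `cec_curve` from [fit_curve()].
#' @param parameters Which parameters to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cec_curve <- function(object,
                               parameters = c("sensitivity", "specificity"),
                               ...) {
  d <- dplyr::filter(object, .data$parameter %in% parameters, !.data$flagged)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$vas, y = .data$estimate,
                                       colour = .data$test)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::facet_grid(parameter ~ stratum) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "VAS pain score", y = "Estimate", colour = "Test") +
    ggplot2::theme_minimal()
  if (!all(is.na(d$lo))) {
    p <- p +
      ggplot2::geom_line(ggplot2::aes(y = .data$lo), linetype = "dashed",
                         linewidth = 0.4, na.rm = TRUE) +
      ggplot2::geom_line(ggplot2::aes(y = .data$hi), linetype = "dashed",
                         linewidth = 0.4, na.rm = TRUE)
  }
  p
}

#' Plot an accuracy table
#'
#' Point estimates with 95% bootstrap intervals, by test and stratum.
#'
#' @param object An `accuracy_table` from [accuracy_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.accuracy_table <- function(object, ...) {
  long <- dplyr::bind_rows(
    dplyr::transmute(object, .data$stratum, .data$test,
                     parameter = "sensitivity",
                     estimate = .data$sensitivity,
                     lo = .data$sens_lo, hi = .data$sens_hi),
    dplyr::transmute(object, .data$stratum, .data$test,
                     parameter = "specificity",
                     estimate = .data$specificity,
                     lo = .data$spec_lo, hi = .data$spec_hi)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$test, y = .data$estimate,
                                     colour = .data$test)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                             na.rm = TRUE) +
    ggplot2::facet_grid(parameter ~ stratum) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Estimate") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}
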