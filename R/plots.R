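#' Plot mean pupil traces by trial type
#'
#' Grand-average baseline-aligned pupil diameter per trial label, with
#' rejected trials excluded.
#'
#' @param object A `pupil_epochs` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pupil_epochs
#' @export
autoplot.pupil_epochs <- function(object, ...) {
  df <- tidy(object)
  df <- dplyr::filter(df, !.data$rejected)
  avg <- dplyr::summarise(
    dplyr::group_by(df, .data$trial_label, .data$time),
    diameter = mean(.data$diameter), .groups = "drop")
  ggplot2::ggplot(avg, ggplot2::aes(.data$time, .data$diameter,
                                    colour = .data$trial_label)) +
    ggplot2::geom_vline(xintercept = c(0, 0.65), linetype = "dotted",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time from first sound (s)",
                  y = "Pupil diameter (px)", colour = "Trial type") +
    ggplot2::theme_minimal()
}

#' Plot a sample-wise PDR effect
#'
#' The t-statistic over time with the FDR-surviving samples marked.
#'
#' @param object A `pdr_effect` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pdr_effect
#' @export
autoplot.pdr_effect <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$t)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = dplyr::filter(df, .data$significant),
                        colour = "red", size = 0.8) +
    ggplot2::labs(title = paste0(object$name, " effect (", object$level,
                                 "): ", object$label),
                  x = "Time from first sound (s)", y = "t statistic") +
    ggplot2::theme_minimal()
}

#' Plot diagnostic metrics with confidence intervals
#'
#' @param object A `diag_metrics` tibble.
#' @param ... Unused.
#' @return A ggplot of point estimates and CIs, in percent.
#' @method autoplot diag_metrics
#' @export
autoplot.diag_metrics <- function(object, ...) {
  df <- dplyr::filter(object, !.data$undefined)
  ggplot2::ggplot(df, ggplot2::aes(.data$metric, .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(x = NULL, y = "Percent") +
    ggplot2::theme_minimal()
}
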