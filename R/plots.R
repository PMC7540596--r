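#' Plot a fit-versus-fairness frontier from a cross-validated run
#'
#' Scatter of the group predictive ratio against cross-validated R2, one
#' point per estimator configuration, the standard way to read off the
#' trade-off between global fit and group fairness. The horizontal reference
#' line marks predictive-ratio parity (exact group-level compensation).
#'
#' @param object A `fair_cv` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fair_cv
#' @export
autoplot.fair_cv <- function(object, ...) {
  dat <- frontier_table(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$R2, y = .data$PR_g,
                                    colour = .data$method)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = expression("Cross-validated" ~ R^2 ~ "(%)"),
                  y = "Predictive ratio, protected group",
                  colour = "Method",
                  title = "Global fit versus group fairness") +
    ggplot2::theme_minimal()
}

#' Plot a simulation-scenario summary frontier
#'
#' As [autoplot.fair_cv()], on the per-configuration replicate means of a
#' scenario run; configurations on the fairness frontier (improved fairness
#' at bounded R2 loss) are drawn solid, the rest hollow.
#'
#' @param object A `fair_scenario` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fair_scenario
#' @export
autoplot.fair_scenario <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$R2, y = .data$PR_g,
                               colour = .data$method,
                               shape = .data$on_frontier)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::labs(x = expression("Cross-validated" ~ R^2 ~ "(%)"),
                  y = "Predictive ratio, protected class",
                  colour = "Method", shape = "On frontier",
                  title = "Simulation summary: fit versus fairness") +
    ggplot2::theme_minimal()
}

#' Plot the largest coefficient changes between two fits
#'
#' Lollipop chart of the flagged top increases and decreases from a
#' [coefficient_change()] report: how a fairness requirement reshapes
#' condition-category payments relative to the reference fit.
#'
#' @param change_report Tibble from [coefficient_change()].
#' @return A ggplot object.
#' @export
plot_coefficient_change <- function(change_report) {
  dat <- change_report |>
    filter(.data$top_change) |>
    mutate(term = stats::reorder(.data$term, .data$change))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$change, y = .data$term,
                                    colour = .data$direction)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$change,
                                       yend = .data$term)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = "Coefficient change (currency)", y = NULL,
                  colour = NULL, title = "Largest coefficient changes") +
    ggplot2::theme_minimal()
}
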