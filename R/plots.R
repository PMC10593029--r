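#' Plot waning VE profiles
#'
#' Draws the three effectiveness measures across waning strata, one panel
#' per example, making non-monotone trends in the conditional measure
#' visible at a glance.
#'
#' @param object A `ve_waning_tbl` from [ve_waning_table()] or
#'   [reproduce_table2()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ve_waning_tbl
#' @export
autoplot.ve_waning_tbl <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(stratum_label = factor(.data$stratum_label,
                                         levels = unique(.data$stratum_label))) |>
    tidyr::pivot_longer(dplyr::all_of(c("ve_s", "ve_h_given_s", "ve_sh")),
                        names_to = "measure", values_to = "ve") |>
    dplyr::mutate(measure = dplyr::recode(.data$measure,
                                          ve_s = "VE against symptoms",
                                          ve_h_given_s = "VE against hosp. | symptomatic",
                                          ve_sh = "VE against hosp."))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$stratum_label,
                                        y = .data$ve,
                                        colour = .data$measure,
                                        group = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "Time since vaccination", y = "Vaccine effectiveness",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if ("example" %in% names(df)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$example))
  }
  p
}

#' Plot a collider-bias grid
#'
#' Crude and stratification-adjusted conditional VE against the benchmark,
#' per grid configuration, with 3-MC-SE error bars on the paired
#' deviations.
#'
#' @param object A `collider_report` from [collider_bias_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot collider_report
#' @export
autoplot.collider_report <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(dplyr::all_of(c("crude", "adjusted")),
                        names_to = "estimator", values_to = "ve") |>
    dplyr::mutate(se = ifelse(.data$estimator == "crude",
                              .data$se_crude, .data$se_adjusted))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$ve,
                                   colour = .data$estimator)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$benchmark),
                        linetype = 2, colour = "grey40") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ve - 3 * .data$se,
                   ymax = .data$ve + 3 * .data$se),
      position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::labs(x = "Configuration",
                  y = "Conditional VE against hospitalization | symptomatic",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a severity pyramid
#'
#' @param object A `severity_pyramid_tbl` from [severity_pyramid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot severity_pyramid_tbl
#' @export
autoplot.severity_pyramid_tbl <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(level = paste0("Pr(", .data$to, " | ", .data$from, ")"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data$risk)) +
    ggplot2::geom_col(width = 0.5, fill = "steelblue") +
    ggplot2::labs(
      x = NULL, y = "Conditional risk",
      subtitle = sprintf("Composed product: %.4f", attr(object, "composite"))
    ) +
    ggplot2::theme_minimal()
}
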