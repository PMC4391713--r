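#' Scatter plot of a concordance fit
#'
#' Manual counts against automated counts with the fitted regression line
#' (solid) and the identity line (dashed).
#'
#' @param object A `concordance_fit` from [ols_concordance()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.concordance_fit <- function(object, ...) {
  df <- object$fit$model
  ggplot2::ggplot(df, ggplot2::aes(x = .data$manual, y = .data$automated)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "#2166AC") +
    ggplot2::labs(
      x = "Manual count", y = "Automated count",
      title = sprintf("slope %.2f, intercept %.2g, r² %.2f",
                      object$slope, object$intercept, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar plot of density estimates with SEM error bars
#'
#' @param densities A tibble from [estimate_densities()] (columns `site`,
#'   `marker`, `method`, `density_mm3`, `sem_mm3`).
#' @return A ggplot object.
#' @export
plot_density_estimates <- function(densities) {
  ggplot2::ggplot(densities,
                  ggplot2::aes(x = .data$marker, y = .data$density_mm3,
                               fill = .data$method)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$density_mm3 - .data$sem_mm3,
                   ymax = .data$density_mm3 + .data$sem_mm3),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$site)) +
    ggplot2::labs(x = NULL, y = "Density (cells/mm³)") +
    ggplot2::theme_minimal()
}

#' Bar plot of flow-vs-in-situ recovery per marker
#'
#' @param recovery A tibble from [compare_recovery()].
#' @return A ggplot object showing recovery and deficit stacked to 100%.
#' @export
plot_recovery <- function(recovery) {
  long <- recovery |>
    select("marker", "recovery_percent", "deficit_percent") |>
    tidyr::pivot_longer(-"marker", names_to = "component",
                        values_to = "percent") |>
    mutate(component = ifelse(.data$component == "recovery_percent",
                              "recovered", "lost"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$marker, y = .data$percent,
                                     fill = .data$component)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::scale_fill_manual(values = c(recovered = "#2166AC",
                                          lost = "#B2182B")) +
    ggplot2::labs(x = NULL, y = "% of in-situ density", fill = NULL) +
    ggplot2::theme_minimal()
}
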