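#' Plot the largest fluxes of a distribution
#'
#' @param object A `flux_distribution` from [solve_fba()].
#' @param n Number of reactions to show, by flux magnitude.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot flux_distribution
#' @export
autoplot.flux_distribution <- function(object, n = 20, ...) {
  df <- tidy(object) |>
    filter(abs(.data$flux) > 1e-6) |>
    arrange(desc(abs(.data$flux))) |>
    head(n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$reaction, abs(.data$flux)),
    y = .data$flux, fill = .data$flux > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL,
                  y = sprintf("flux (%s)", object$basis),
                  title = "Largest reaction fluxes") +
    ggplot2::theme_minimal()
}

#' Plot a cofactor ledger
#'
#' Producer and consumer shares of one metabolite, side by side.
#'
#' @param object A [cofactor_ledger()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cofactor_ledger
#' @export
autoplot.cofactor_ledger <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$reaction, .data$rate),
    y = .data$rate)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~side, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "rate (per 100 glucose)",
                  title = sprintf("%s (%s) production and consumption",
                                  attr(object, "metabolite"),
                                  attr(object, "compartment"))) +
    ggplot2::theme_minimal()
}

#' Plot a scenario comparison
#'
#' Scatter of per-reaction fluxes in scenario B against scenario A, with the
#' up/down classification mapped to colour.
#'
#' @param object A [compare_scenarios()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot scenario_comparison
#' @export
autoplot.scenario_comparison <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$flux_a, y = .data$flux_b,
                                   colour = .data$class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "flux in A (per 100 glucose)",
                  y = "flux in B (per 100 glucose)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
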