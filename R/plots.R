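#' Community composition bar chart
#'
#' Stacked bars of provider counts by specialty group within each network
#' community (the community-composition figure).
#'
#' @param profiles provider profile tibble (needs `community` and
#'   `specialty_group`).
#' @return a ggplot object.
#' @export
plot_community_composition <- function(profiles) {
  dat <- profiles |>
    dplyr::filter(!is.na(.data$community)) |>
    dplyr::count(.data$community, .data$specialty_group)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$community, y = .data$n,
                                    fill = .data$specialty_group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Network community", y = "Providers",
                  fill = "Specialty") +
    ggplot2::theme_minimal()
}

#' Degree distribution histogram
#'
#' @param profiles provider profile tibble (needs `degree`).
#' @param bins histogram bin count.
#' @return a ggplot object.
#' @export
plot_degree_distribution <- function(profiles, bins = 40) {
  ggplot2::ggplot(profiles, ggplot2::aes(x = .data$degree)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::labs(x = "Network degree (providers sharing ≥ threshold patients)",
                  y = "Providers") +
    ggplot2::theme_minimal()
}

#' Coefficient plot for a fitted CoC model
#'
#' Point estimates with 95% Wald intervals for the fixed effects.
#'
#' @param object a `coc_model_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.coc_model_fit <- function(object, ...) {
  dat <- object$coefficients |>
    dplyr::filter(.data$term != "(Intercept)") |>
    dplyr::mutate(lo = .data$estimate - 1.96 * .data$std_error,
                  hi = .data$estimate + 1.96 * .data$std_error)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo,
                                          xmax = .data$hi)) +
    ggplot2::labs(x = "Estimate (95% Wald interval)", y = NULL,
                  title = paste0("Provider CoC model ", object$model)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
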