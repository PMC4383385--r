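#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest plot of mediation estimates
#'
#' @param object A `mediation_estimates` tibble.
#' @param ... Unused.
#' @return A ggplot: point estimates with interval whiskers (delta/bootstrap
#'   intervals where available, otherwise ±2 Monte Carlo SEs).
#' @export
autoplot.mediation_estimates <- function(object, ...) {
  d <- tibble::as_tibble(object)
  if (!"ci_low" %in% names(d) && "mc_se" %in% names(d)) {
    d$ci_low <- d$estimate - 2 * d$mc_se
    d$ci_high <- d$estimate + 2 * d$mc_se
  }
  d$estimand <- factor(d$estimand, levels = rev(c("tce", "pnde", "tnie",
                                                  "cde")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$estimand)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::labs(
      x = "effect (outcome units, exposure 1 vs 0)", y = NULL,
      title = sprintf("Mediation effects (%s, %s)", attr(object, "method"),
                      attr(object, "assumption"))
    ) +
    ggplot2::theme_minimal()
}

#' Coefficient plot for the identification diagnostics
#'
#' @param object An `identification_report`.
#' @param ... Unused.
#' @return A ggplot of the unconstrained outcome-model coefficients with
#'   approximate 95% intervals; the terms whose nullity the two
#'   identification assumptions require are highlighted.
#' @export
autoplot.identification_report <- function(object, ...) {
  d <- object$coefficients
  d <- d[d$term != "(Intercept)", ]
  d$constraint <- dplyr::case_when(
    d$term == "xm" ~ "Robins-Greenland requires 0",
    d$term %in% c("xl", "l2") ~ "Petersen requires 0",
    TRUE ~ "unconstrained"
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term,
                                  colour = .data$constraint)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$std.error,
      xmax = .data$estimate + 1.96 * .data$std.error)) +
    ggplot2::labs(x = "coefficient (outcome equation)", y = NULL,
                  colour = NULL,
                  title = "Unconstrained outcome model: identification terms") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
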