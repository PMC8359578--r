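#' Plot biological against chronological age
#'
#' Scatter of each biological-age estimate against chronological age with
#' the identity line; deaths over follow-up are highlighted.
#'
#' @param object A `"ba_pipeline"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ba_pipeline
#' @export
autoplot.ba_pipeline <- function(object, ...) {
  df <- object$predictions |>
    tidyr::pivot_longer(
      dplyr::any_of(c("ba_years", "ba_e_years", "ba_ec_years")),
      names_to = "estimator", values_to = "bioage"
    ) |>
    dplyr::mutate(estimator = dplyr::recode(.data$estimator,
                                            ba_years = "BA (PCA)",
                                            ba_e_years = "BA_E (KDM)",
                                            ba_ec_years = "BA_EC (KDM)"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ca_years, y = .data$bioage)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50",
                         linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$status == "all_cause_death"),
                        alpha = 0.4, size = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "steelblue",
                                            `TRUE` = "firebrick"),
                                 labels = c("alive", "death"),
                                 name = NULL) +
    ggplot2::facet_wrap(ggplot2::vars(.data$estimator)) +
    ggplot2::labs(x = "chronological age (years)",
                  y = "biological age (years)") +
    ggplot2::theme_minimal()
}
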