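# ggplot2 displays for the main result types.

#' Plot per-subcategory evaluation metrics
#'
#' Dot plot of precision, recall and F per subcategory, with the macro
#' overall values as vertical reference lines.
#'
#' @param object An `ineads_eval` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ineads_eval <- function(object, ...) {
  df <- object$by_category %>%
    tidyr::pivot_longer(c("precision", "recall", "f_score"),
                        names_to = "metric", values_to = "value") %>%
    filter(!is.na(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$subcategory,
                                   colour = .data$metric)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "score", y = NULL, colour = NULL,
                  title = "Note-level detection performance by subcategory") +
    ggplot2::theme_minimal()
}

#' Plot admission-level subcategory prevalence
#'
#' Fraction of admissions whose notes document each subcategory, coloured
#' by the direction of INEADS potential.
#'
#' @param profiles Profile tibble from [aggregate_admissions()].
#' @return A ggplot object.
#' @export
plot_subcategory_prevalence <- function(profiles) {
  n_adm <- nrow(profiles)
  df <- tibble(subcategory = unlist(profiles$subcategories)) %>%
    count(.data$subcategory) %>%
    mutate(fraction = n / n_adm) %>%
    left_join(subcategory_schema(), by = "subcategory")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction,
                                   y = stats::reorder(.data$subcategory, .data$fraction),
                                   fill = .data$potential)) +
    ggplot2::geom_col() +
    ggplot2::scale_x_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = "admissions with subcategory", y = NULL,
                  fill = "INEADS potential",
                  title = "Subcategory documentation at the admission level") +
    ggplot2::theme_minimal()
}

#' Plot cohort characteristics
#'
#' Percentage bars per cohort for one characteristic of a cohort summary.
#'
#' @param summary An `ineads_cohort_summary` from [summarize_cohorts()].
#' @param characteristic Which characteristic to show (e.g. `"insurance"`,
#'   `"expired_in_followup"`).
#' @return A ggplot object.
#' @export
plot_cohort_characteristic <- function(summary, characteristic = "insurance") {
  df <- as_tibble(summary) %>%
    filter(.data$characteristic == !!characteristic, !is.na(.data$pct))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data$pct,
                                   fill = .data$cohort)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% of cohort", fill = NULL,
                  title = paste0("Cohort comparison: ", characteristic)) +
    ggplot2::theme_minimal()
}
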