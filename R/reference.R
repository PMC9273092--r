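# Published reference validation results shipped with the package, used to
# regression-check the evaluation arithmetic (F from precision/recall,
# macro averaging, percentage computation) against an independent,
# externally reported benchmark of this detection approach.

#' Reference validation metrics
#'
#' Per-subcategory precision, recall and F from a published 300-note
#' gold-standard validation of this detection approach, plus the macro
#' overall row. Two subcategories (caregiver support, advance directives
#' unavailable) had no observations in that sample and are reported as
#' absent (`NA`). Percentages of documentation are over the 184 notes that
#' carried at least one label.
#'
#' @return A list with `by_category` (17-row tibble: `subcategory`,
#'   `gold_n`, `gold_pct`, `precision`, `recall`, `f_score`) and `overall`
#'   (one-row tibble).
#' @export
reference_metrics <- function() {
  path <- system.file("extdata", "reference_metrics.tsv", package = "ineads",
                      mustWork = TRUE)
  tab <- readr::read_tsv(path, col_types = "cddddd", progress = FALSE)
  list(
    by_category = tab[tab$subcategory != "overall", , drop = FALSE],
    overall = tab[tab$subcategory == "overall", , drop = FALSE]
  )
}

#' Reference corpus-level counts
#'
#' Published numerator/denominator pairs (with their printed percentages)
#' from a full-corpus application of this approach to roughly 418,000
#' critical-care notes over 23,904 adult admissions: fractions of notes and
#' admissions with at least one subcategory, the reduced-signal and
#' possibility-cohort fractions, and full-cohort follow-up mortality.
#'
#' @return A tibble with `quantity`, `numerator`, `denominator`,
#'   `printed_pct`.
#' @export
reference_counts <- function() {
  path <- system.file("extdata", "reference_counts.tsv", package = "ineads",
                      mustWork = TRUE)
  readr::read_tsv(path, col_types = "cddd", progress = FALSE)
}
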