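# End-to-end convenience: annotate -> aggregate -> classify -> summarize.

#' Run the full detection pipeline
#'
#' Annotates every note with the lexicon, aggregates to admission
#' profiles, applies the cohort rules, and summarizes cohort
#' characteristics.
#'
#' @param notes Notes tibble ([read_notes()] schema).
#' @param admissions Admissions tibble ([read_admissions()] schema).
#' @param lexicon Lexicon (default: the shipped seed lexicon).
#' @param stopwords Stopword list.
#' @param negation Negation configuration.
#' @return A list of class `ineads_pipeline` with `annotations`
#'   (`ineads_annotations`), `profiles` (classified admission profiles),
#'   `cohort_summary`, and `comparisons` (possibility and, when non-empty,
#'   high-likelihood cohort tests vs the full cohort).
#' @export
run_pipeline <- function(notes, admissions, lexicon = seed_default_lexicon(),
                         stopwords = default_stopwords(),
                         negation = negation_config()) {
  ann <- annotate_corpus(notes, lexicon, stopwords, negation)
  profiles <- aggregate_admissions(ann, notes, admissions) %>%
    classify_ineads()
  summary <- summarize_cohorts(admissions, profiles)
  comparisons <- list()
  if (any(profiles$label >= "possibility")) {
    comparisons$possibility <- compare_cohorts(admissions, profiles, "possibility")
  }
  if (any(profiles$label == "high_likelihood")) {
    comparisons$high_likelihood <-
      compare_cohorts(admissions, profiles, "high_likelihood")
  }
  structure(
    list(annotations = ann, profiles = profiles, cohort_summary = summary,
         comparisons = comparisons),
    class = "ineads_pipeline"
  )
}

#' @export
print.ineads_pipeline <- function(x, ...) {
  s <- x$annotations$summary
  n_pos <- sum(x$profiles$label >= "possibility")
  n_high <- sum(x$profiles$label == "high_likelihood")
  cat("<ineads pipeline>\n")
  cat(sprintf("  notes with >=1 subcategory: %d/%d (%.0f%%)\n",
              s$n_notes_with_subcategory, s$n_notes, 100 * s$fraction))
  cat(sprintf("  admissions: %d; possibility cohort: %d (%.1f%%); high likelihood: %d\n",
              nrow(x$profiles), n_pos, 100 * n_pos / nrow(x$profiles), n_high))
  invisible(x)
}
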