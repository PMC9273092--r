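# Scoring system annotations against gold-standard chart review:
# per-subcategory note-level precision (PPV), recall (sensitivity) and F,
# an unweighted macro overall row, documentation frequencies, and Cohen's
# kappa for inter-annotator agreement.

#' F-score (harmonic mean of precision and recall)
#'
#' @param precision,recall Numeric vectors in `[0, 1]`.
#' @return `2 P R / (P + R)`, elementwise; 0 where `P + R = 0`.
#' @export
f_score <- function(precision, recall) {
  if (any(precision < 0 | precision > 1 | recall < 0 | recall > 1,
          na.rm = TRUE)) {
    abort("precision and recall must lie in [0, 1]")
  }
  denom <- precision + recall
  out <- ifelse(denom > 0, 2 * precision * recall / denom, 0)
  out[is.na(precision) | is.na(recall)] <- NA_real_
  out
}

as_label_pairs <- function(x) {
  if (inherits(x, "ineads_annotations")) return(x$note_subcategories)
  x <- as_tibble(x)
  if ("negated" %in% names(x)) return(note_subcategories(x))
  distinct(x, .data$note_id, .data$subcategory)
}

#' Evaluate system annotations against gold labels
#'
#' Note-level binary comparison per subcategory: a true positive is a note
#' where both system and gold assign the subcategory; false positives are
#' system-only, false negatives gold-only. Per-category precision
#' (TP/(TP+FP)), recall (TP/(TP+FN)) and F are reported, and the overall
#' row is the unweighted macro mean over categories with at least one gold
#' or predicted observation (categories with none are reported as absent,
#' not averaged in).
#'
#' @param system System output: an `ineads_annotations` object or a tibble
#'   of (`note_id`, `subcategory`) pairs (negated mentions are dropped if a
#'   `negated` column is present).
#' @param gold Gold labels: tibble of (`note_id`, `subcategory`) pairs;
#'   rows with `NA` subcategory mark reviewed notes with no label.
#' @param note_ids The gold universe of reviewed note ids (default: the
#'   note ids appearing in `gold`). A system note outside this universe is
#'   an error.
#' @return An object of class `ineads_eval`: list with `by_category`
#'   (tibble: `subcategory`, `gold_n`, `gold_pct`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f_score`), `overall` (one-row tibble of macro
#'   means), `n_notes`, `n_labeled_notes`.
#' @export
evaluate_annotations <- function(system, gold, note_ids = unique(gold$note_id)) {
  sys <- as_label_pairs(system)
  gld <- as_tibble(gold) %>%
    filter(!is.na(.data$subcategory)) %>%
    distinct(.data$note_id, .data$subcategory)
  outside <- setdiff(sys$note_id, note_ids)
  if (length(outside) > 0) {
    abort(paste0("system output contains note(s) absent from the gold ",
                 "universe: ", paste(head(outside, 5), collapse = ", ")))
  }
  sys <- sys[sys$note_id %in% note_ids, , drop = FALSE]

  cats <- sort(union(unique(gld$subcategory), unique(sys$subcategory)))
  n_labeled <- length(unique(gld$note_id))
  by_cat <- purrr::map(cats, function(ct) {
    g <- gld$note_id[gld$subcategory == ct]
    s <- sys$note_id[sys$subcategory == ct]
    tp <- length(intersect(g, s))
    fp <- length(setdiff(s, g))
    fn <- length(setdiff(g, s))
    tibble(
      subcategory = ct, gold_n = length(g),
      gold_pct = if (n_labeled > 0) round(100 * length(g) / n_labeled, 1) else NA_real_,
      tp = tp, fp = fp, fn = fn,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      f_score = if (tp + fp + fn > 0) {
        p <- if (tp + fp > 0) tp / (tp + fp) else 0
        r <- if (tp + fn > 0) tp / (tp + fn) else 0
        f_score(p, r)
      } else NA_real_
    )
  }) %>% bind_rows()

  overall <- tibble(
    n_categories = nrow(by_cat),
    precision = mean(by_cat$precision, na.rm = TRUE),
    recall = mean(by_cat$recall, na.rm = TRUE),
    f_score = mean(by_cat$f_score, na.rm = TRUE)
  )
  structure(
    list(by_category = by_cat, overall = overall,
         n_notes = length(note_ids), n_labeled_notes = n_labeled),
    class = "ineads_eval"
  )
}

#' @export
print.ineads_eval <- function(x, ...) {
  cat("<ineads evaluation> ", x$n_notes, " notes (", x$n_labeled_notes,
      " with >=1 gold label), ", nrow(x$by_category), " subcategories\n",
      sep = "")
  cat(sprintf("overall (macro): precision %.2f, recall %.2f, F %.2f\n",
              x$overall$precision, x$overall$recall, x$overall$f_score))
  invisible(x)
}

#' @describeIn evaluate_annotations Per-category metric rows, one tibble
#'   row per subcategory.
#' @param x An `ineads_eval` object.
#' @param ... Unused.
#' @export
tidy.ineads_eval <- function(x, ...) x$by_category

#' @describeIn evaluate_annotations One-row macro summary.
#' @export
glance.ineads_eval <- function(x, ...) {
  dplyr::bind_cols(x$overall,
                   tibble(n_notes = x$n_notes,
                          n_labeled_notes = x$n_labeled_notes))
}

#' Macro-average of per-category metrics
#'
#' Unweighted means of precision, recall and F over categories with
#' observations; `NA` entries (categories without observations) are
#' excluded from the mean.
#'
#' @param metrics Tibble with `precision`, `recall`, `f_score` columns.
#' @return One-row tibble with macro `precision`, `recall`, `f_score`.
#' @export
macro_average <- function(metrics) {
  tibble(
    precision = mean(metrics$precision, na.rm = TRUE),
    recall = mean(metrics$recall, na.rm = TRUE),
    f_score = mean(metrics$f_score, na.rm = TRUE)
  )
}

#' Cohen's kappa for two binary annotators
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with the standard marginal expected
#' agreement. In the degenerate case `p_e = 1` (both annotators constant
#' and equal) kappa is undefined and is reported as 1 with attribute
#' `degenerate = TRUE`.
#'
#' @param a,b Logical (or 0/1) vectors of equal length, one element per
#'   note.
#' @return A double with attributes `p_o`, `p_e`, `degenerate`.
#' @export
cohens_kappa <- function(a, b) {
  a <- as.logical(a)
  b <- as.logical(b)
  if (length(a) != length(b)) abort("annotator vectors differ in length")
  if (length(a) == 0) abort("empty annotator vectors")
  n <- length(a)
  p_o <- mean(a == b)
  p_yes <- mean(a) * mean(b)
  p_no <- mean(!a) * mean(!b)
  p_e <- p_yes + p_no
  if (abs(1 - p_e) < .Machine$double.eps^0.5) {
    k <- if (p_o == 1) 1 else 0
    return(structure(k, p_o = p_o, p_e = p_e, degenerate = TRUE))
  }
  structure((p_o - p_e) / (1 - p_e), p_o = p_o, p_e = p_e, degenerate = FALSE)
}

#' Per-subcategory documentation frequency
#'
#' Counts the notes documenting each subcategory; percentages are computed
#' over the notes carrying at least one label (not over all reviewed
#' notes), matching the convention of reporting the labeled subset as 100%.
#'
#' @param gold Tibble of (`note_id`, `subcategory`) gold pairs.
#' @return A tibble `subcategory`, `n`, `pct`, sorted by `n` descending,
#'   with attribute `n_labeled_notes`.
#' @export
frequency_table <- function(gold) {
  gld <- as_tibble(gold) %>%
    filter(!is.na(.data$subcategory)) %>%
    distinct(.data$note_id, .data$subcategory)
  n_labeled <- length(unique(gld$note_id))
  out <- gld %>%
    count(.data$subcategory, name = "n") %>%
    mutate(pct = round(100 * n / n_labeled, 1)) %>%
    arrange(dplyr::desc(n), .data$subcategory)
  attr(out, "n_labeled_notes") <- n_labeled
  out
}

#' Read / write gold labels as TSV
#'
#' Schema: `note_id`, `subcategory` (blank subcategory = reviewed note with
#' no label).
#'
#' @param gold Gold-label tibble.
#' @param path File path.
#' @return `write_gold_labels` the input invisibly; `read_gold_labels` a
#'   tibble.
#' @export
write_gold_labels <- function(gold, path) {
  readr::write_tsv(gold, path, na = "")
  invisible(gold)
}

#' @rdname write_gold_labels
#' @export
read_gold_labels <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}
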