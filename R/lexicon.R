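# The 17-subcategory vocabulary: three domains (surrogate decision makers,
# advance directives, decisional capacity), each subcategory annotated with
# the direction of INEADS potential it signals. Five "social" subcategories
# with elevated potential drive the cohort rules.

#' Subcategory schema
#'
#' The fixed set of 17 subcategories: 12 under surrogate decision makers,
#' 4 under advance directives, 1 under decisional capacity; 11 signal
#' reduced and 6 elevated potential for being INEADS. Exactly five —
#' unmarried, living alone, transitionally situated, surrogate decision
#' maker unidentified, advance directives unavailable — are the "social
#' elevated" subcategories used by the cohort rules; lacking capacity is
#' elevated but not social.
#'
#' @return A tibble with columns `subcategory`, `domain`, `potential`,
#'   `is_social_elevated`.
#' @export
subcategory_schema <- function() {
  sdm <- "surrogate_decision_makers"
  ad <- "advance_directives"
  dc <- "decisional_capacity"
  tibble::tribble(
    ~subcategory, ~domain, ~potential, ~is_social_elevated,
    "married", sdm, "reduced", FALSE,
    "partnered", sdm, "reduced", FALSE,
    "relatives_unknown_involvement", sdm, "reduced", FALSE,
    "caregiver_support", sdm, "reduced", FALSE,
    "living_with_others", sdm, "reduced", FALSE,
    "community_connection", sdm, "reduced", FALSE,
    "religious_connections", sdm, "reduced", FALSE,
    "surrogate_identified", sdm, "reduced", FALSE,
    "unmarried", sdm, "elevated", TRUE,
    "living_alone", sdm, "elevated", TRUE,
    "transitionally_situated", sdm, "elevated", TRUE,
    "surrogate_unidentified", sdm, "elevated", TRUE,
    "palliative_care", ad, "reduced", FALSE,
    "hospice", ad, "reduced", FALSE,
    "advance_directives_available", ad, "reduced", FALSE,
    "advance_directives_unavailable", ad, "elevated", TRUE,
    "lacking_capacity", dc, "elevated", FALSE
  )
}

#' The five social subcategories with elevated INEADS potential
#' @return Character vector of five subcategory names.
#' @export
social_elevated_subcategories <- function() {
  s <- subcategory_schema()
  s$subcategory[s$is_social_elevated]
}

#' Subcategories signalling reduced INEADS potential
#' @return Character vector of eleven subcategory names.
#' @export
reduced_subcategories <- function() {
  s <- subcategory_schema()
  s$subcategory[s$potential == "reduced"]
}

seed_terms <- function() {
  list(
    married = c(
      "husband", "wife", "spouse", "married", "surgical consent signed by husband"
    ),
    partnered = c(
      "girlfriend", "boyfriend", "significant other", "fiancé",
      "fiancée", "fiance", "fiancee", "domestic partner"
    ),
    relatives_unknown_involvement = c(
      "son", "daughter", "aunt", "uncle", "brother", "brothers", "sister",
      "mother", "father", "niece", "nephew", "cousin", "grandson",
      "granddaughter", "complicated family dynamics"
    ),
    caregiver_support = c(
      "primary caregiver", "sole caregiver", "main caregiver",
      "caregiver at home"
    ),
    living_with_others = c(
      "daughter lives nearby", "roommate", "lives with", "lives with family",
      "lives with roommate", "lives with wife", "lives with husband"
    ),
    community_connection = c(
      "supportive neighbors", "friend who assists", "senior center",
      "many friends", "friends in to visit", "supportive friends"
    ),
    religious_connections = c(
      "their rabbi", "clergy involved", "practicing catholic", "chaplain",
      "rabbi", "clergy", "sacrament of the sick", "pastor"
    ),
    surrogate_identified = c(
      "family meeting occurred", "spoke with daughter", "family decided",
      "family meeting", "family was called", "next of kin notified",
      "family at bedside"
    ),
    unmarried = c(
      "recently widowed", "estranged from his wife", "estranged from her husband",
      "never married", "divorced", "widowed", "widower", "unmarried"
    ),
    living_alone = c(
      "lives alone", "living alone", "lives independently", "without caregiver",
      "lives by himself", "lives by herself"
    ),
    transitionally_situated = c(
      "currently homeless", "half-way house", "halfway house", "incarcerated",
      "homeless", "homeless now", "shelter", "undomiciled"
    ),
    surrogate_unidentified = c(
      "cannot find family", "family member did not respond", "family unreachable",
      "no contact from family", "unable to reach family", "no known family",
      "no family contact", "no next of kin"
    ),
    palliative_care = c(
      "palliative care", "ethics palliative care", "palliative care consulted",
      "palliative services", "palliative", "palliative care present"
    ),
    hospice = c(
      "hospice", "moving toward hospice", "arrange home hospice",
      "hospice nurses", "home with hospice", "discharge home with hospice"
    ),
    advance_directives_available = c(
      "sister hcp", "contact daughter hcp", "code status dnr/dni", "dnr",
      "dni", "hcp", "health care proxy", "health care proxy appointed",
      "healthcare proxy", "living will on file", "molst", "polst"
    ),
    advance_directives_unavailable = c(
      "no living will", "no advance directives", "no advance directive",
      "no healthcare proxy", "no health care proxy", "no hcp", "no molst"
    ),
    lacking_capacity = c(
      "aox disoriented", "loss of executive function", "impaired judgement",
      "dementia", "lacks capacity", "lacking capacity",
      "unable to make decisions", "altered mental status", "obtunded",
      "unresponsive", "delirium", "severe dementia"
    )
  )
}

#' Normalize a term with the corpus tokenizer
#'
#' Lexicon terms are stored pre-normalized with exactly the same tokenizer
#' and stopword list used on notes, so matching is tokenizer-consistent
#' ("sacrament of the sick" is stored as "sacrament sick" if "of"/"the" are
#' stopwords, and matches the same normalized note text).
#'
#' @param term Character vector of raw terms.
#' @param stopwords Stopword list; must match the one used on notes.
#' @return Character vector of normalized, space-joined token sequences
#'   (`NA` where nothing survives normalization).
#' @export
normalize_term <- function(term, stopwords = default_stopwords()) {
  vapply(term, function(tm) {
    tk <- tokenize_text(tm, stopwords)
    if (nrow(tk) == 0) NA_character_ else paste(tk$token, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

new_lexicon <- function(entries, version = "0") {
  entries <- as_tibble(entries)
  structure(entries, class = c("ineads_lexicon", class(entries)),
            version = version)
}

#' Build the default seed lexicon
#'
#' The shipped vocabulary: for each of the 17 subcategories, the sample
#' terms of the subcategory schema plus curated obvious variants, each
#' tagged `provenance = "seed"`. Terms are normalized with the corpus
#' tokenizer at construction time.
#'
#' @param stopwords Stopword list used for term normalization.
#' @return A lexicon: a tibble with columns `term` (normalized), `subcategory`,
#'   `domain`, `potential`, `provenance`, carrying class `ineads_lexicon`.
#' @export
seed_default_lexicon <- function(stopwords = default_stopwords()) {
  terms <- seed_terms()
  entries <- purrr::imap(terms, function(tms, sub) {
    tibble(term = normalize_term(tms, stopwords), subcategory = sub)
  }) %>%
    bind_rows() %>%
    filter(!is.na(.data$term)) %>%
    distinct(.data$term, .data$subcategory) %>%
    left_join(subcategory_schema(), by = "subcategory") %>%
    mutate(provenance = "seed") %>%
    select("term", "subcategory", "domain", "potential", "provenance") %>%
    arrange(.data$subcategory, .data$term)
  new_lexicon(entries, version = "seed-1")
}

#' @export
print.ineads_lexicon <- function(x, ...) {
  cat("<ineads lexicon> ", nrow(x), " entries across ",
      length(unique(x$subcategory)), " subcategories (version ",
      attr(x, "version"), ")\n", sep = "")
  NextMethod()
}

#' Look up a term in a lexicon
#'
#' @param lexicon A lexicon tibble.
#' @param term Raw term (normalized before lookup).
#' @param stopwords Stopword list for normalization.
#' @return The matching lexicon rows (zero rows if absent).
#' @export
lexicon_lookup <- function(lexicon, term, stopwords = default_stopwords()) {
  nt <- normalize_term(term, stopwords)
  as_tibble(lexicon)[lexicon$term %in% nt, , drop = FALSE]
}

#' Save / load a lexicon as TSV
#'
#' The TSV schema is `term`, `subcategory`, `domain`, `potential`,
#' `provenance`. Loading validates subcategory names against the schema and
#' deduplicates repeated (term, subcategory) pairs with a warning, so that
#' `load_lexicon(save_lexicon(x))` is the identity on entry sets.
#'
#' @param lexicon A lexicon tibble.
#' @param path TSV file path.
#' @return `save_lexicon` returns the lexicon invisibly; `load_lexicon`
#'   returns a lexicon.
#' @export
save_lexicon <- function(lexicon, path) {
  out <- as_tibble(lexicon)[, c("term", "subcategory", "domain", "potential",
                                "provenance")]
  readr::write_tsv(out, path)
  invisible(lexicon)
}

#' @rdname save_lexicon
#' @export
load_lexicon <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  needed <- c("term", "subcategory")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("lexicon TSV is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  schema <- subcategory_schema()
  bad <- setdiff(unique(raw$subcategory), schema$subcategory)
  if (length(bad) > 0) {
    abort(paste0(
      "unknown subcategory name(s): ", paste(bad, collapse = ", "),
      "\nvalid names: ", paste(schema$subcategory, collapse = ", ")
    ))
  }
  if (!"provenance" %in% names(raw)) raw$provenance <- "seed"
  n_before <- nrow(raw)
  out <- raw %>%
    select("term", "subcategory", "provenance") %>%
    distinct(.data$term, .data$subcategory, .keep_all = TRUE) %>%
    left_join(schema, by = "subcategory") %>%
    select("term", "subcategory", "domain", "potential", "provenance")
  if (nrow(out) < n_before) {
    warn(paste0("lexicon TSV contained ", n_before - nrow(out),
                " duplicate (term, subcategory) pair(s); deduplicated"))
  }
  new_lexicon(out, version = "loaded")
}

#' Validate a lexicon
#'
#' Checks for empty terms, duplicate (term, subcategory) pairs, terms whose
#' content is entirely stopwords, and terms shared across subcategories
#' (allowed but flagged).
#'
#' @param lexicon A lexicon tibble.
#' @param stopwords Stopword list.
#' @return A tibble with columns `level` (`"error"`/`"warning"`), `check`,
#'   `detail`; zero rows when the lexicon is clean.
#' @export
validate_lexicon <- function(lexicon, stopwords = default_stopwords()) {
  lx <- as_tibble(lexicon)
  report <- list()
  empty <- is.na(lx$term) | !nzchar(stringr::str_trim(lx$term))
  if (any(empty)) {
    report <- c(report, list(tibble(
      level = "error", check = "empty_term",
      detail = paste0(sum(empty), " empty term(s)")
    )))
  }
  dup <- lx %>% count(.data$term, .data$subcategory) %>% filter(n > 1)
  if (nrow(dup) > 0) {
    report <- c(report, list(tibble(
      level = "error", check = "duplicate_entry",
      detail = paste(dup$term, dup$subcategory, sep = "/", collapse = "; ")
    )))
  }
  stop_only <- !empty & vapply(lx$term, function(tm) {
    toks <- strsplit(tm, " ", fixed = TRUE)[[1]]
    length(toks) > 0 && all(toks %in% stopwords)
  }, logical(1))
  if (any(stop_only)) {
    report <- c(report, list(tibble(
      level = "error", check = "stopword_only_term",
      detail = paste(unique(lx$term[stop_only]), collapse = "; ")
    )))
  }
  cross <- lx %>%
    distinct(.data$term, .data$subcategory) %>%
    count(.data$term) %>%
    filter(n > 1)
  if (nrow(cross) > 0) {
    report <- c(report, list(tibble(
      level = "warning", check = "cross_subcategory_term",
      detail = paste(cross$term, collapse = "; ")
    )))
  }
  if (length(report) == 0) {
    return(tibble(level = character(), check = character(), detail = character()))
  }
  bind_rows(report)
}
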