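# Negation-aware lexicon matching. Mentions are maximal matches of
# normalized lexicon token sequences against normalized note tokens;
# overlapping candidates are resolved longest-match-first, then leftmost.
# Negation follows a NegEx-style trigger/scope model.

#' Default negation configuration
#'
#' Forward triggers negate a mention when they occur within `scope` tokens
#' before its start; backward triggers within `scope` tokens after its end.
#' Scope is broken at sentence boundaries and at the conjunction "but".
#' Mentions whose matched term itself begins with a negation token (e.g.
#' "no living will", "no contact from family") are exempt: the negation is
#' part of the concept, not a denial of it.
#'
#' @param scope Token window for triggers (default 6).
#' @param forward,backward Trigger token vectors.
#' @param scope_breakers Tokens that end a negation scope.
#' @return A list with elements `forward`, `backward`, `scope`,
#'   `scope_breakers`.
#' @export
negation_config <- function(scope = 6,
                            forward = c(
                              "no", "not", "never", "denies", "denied",
                              "denying", "deny", "without", "declines",
                              "declined", "refuses", "refused", "negative",
                              "lacks", "lacking"
                            ),
                            backward = c(
                              "unlikely", "doubtful", "unconfirmed",
                              "refuted", "excluded"
                            ),
                            scope_breakers = "but") {
  stopifnot(scope >= 1)
  list(forward = forward, backward = backward, scope = as.integer(scope),
       scope_breakers = scope_breakers)
}

# pre-split lexicon terms, ordered for longest-match-first resolution
lexicon_index <- function(lexicon) {
  lx <- as_tibble(lexicon)
  lx <- lx[!is.na(lx$term) & nzchar(lx$term), , drop = FALSE]
  token_lists <- strsplit(lx$term, " ", fixed = TRUE)
  tibble(
    term = lx$term,
    subcategory = lx$subcategory,
    tokens = token_lists,
    n_tokens = lengths(token_lists),
    first = vapply(token_lists, `[`, character(1), 1)
  )
}

#' Find lexicon mentions in one tokenized note
#'
#' Enumerates every position where a lexicon term's token sequence occurs,
#' then resolves overlaps longest-match-first, then leftmost (ties broken by
#' subcategory name): an accepted mention consumes its tokens, so a token
#' participates in at most one mention. Negation is not applied here.
#'
#' @param tokens Token tibble for a single note ([tokenize_text()] output,
#'   or a [tokenize_notes()] slice).
#' @param lexicon A lexicon tibble.
#' @return A tibble of mentions: `subcategory`, `term`, `token_start`,
#'   `token_end` (1-based inclusive token indices), `char_start`, `char_end`,
#'   `negated` (all `FALSE` here).
#' @export
find_mentions <- function(tokens, lexicon) {
  idx <- if (inherits(lexicon, "ineads_lexicon_index")) lexicon else lexicon_index(lexicon)
  empty <- tibble::new_tibble(
    list(subcategory = character(), term = character(),
         token_start = integer(), token_end = integer(),
         char_start = integer(), char_end = integer(), negated = logical()),
    nrow = 0L
  )
  nt <- nrow(tokens)
  if (nt == 0 || nrow(idx) == 0) return(empty)
  toks <- tokens$token

  # only terms whose first token occurs in the note can match
  idx <- idx[idx$first %in% toks, , drop = FALSE]
  if (nrow(idx) == 0) return(empty)

  cand <- list()
  for (i in seq_len(nrow(idx))) {
    L <- idx$n_tokens[i]
    if (L > nt) next
    starts <- which(toks == idx$first[i])
    starts <- starts[starts + L - 1 <= nt]
    if (L > 1 && length(starts) > 0) {
      tt <- idx$tokens[[i]]
      ok <- vapply(starts, function(s) all(toks[s:(s + L - 1)] == tt), logical(1))
      starts <- starts[ok]
    }
    if (length(starts) > 0) {
      cand[[length(cand) + 1]] <- list(
        subcategory = rep(idx$subcategory[i], length(starts)),
        term = rep(idx$term[i], length(starts)),
        token_start = as.integer(starts),
        token_end = as.integer(starts + L - 1L),
        len = rep(L, length(starts))
      )
    }
  }
  if (length(cand) == 0) return(empty)
  cs <- list(
    subcategory = unlist(lapply(cand, `[[`, "subcategory")),
    term = unlist(lapply(cand, `[[`, "term")),
    token_start = unlist(lapply(cand, `[[`, "token_start")),
    token_end = unlist(lapply(cand, `[[`, "token_end")),
    len = unlist(lapply(cand, `[[`, "len"))
  )
  ord <- order(-cs$len, cs$token_start, cs$subcategory, cs$term)

  consumed <- logical(nt)
  keep <- logical(length(ord))
  for (j in seq_along(ord)) {
    i <- ord[j]
    span <- cs$token_start[i]:cs$token_end[i]
    if (!any(consumed[span])) {
      keep[j] <- TRUE
      consumed[span] <- TRUE
    }
  }
  sel <- ord[keep]
  sel <- sel[order(cs$token_start[sel])]
  tibble::new_tibble(
    list(
      subcategory = cs$subcategory[sel], term = cs$term[sel],
      token_start = cs$token_start[sel], token_end = cs$token_end[sel],
      char_start = as.integer(tokens$start[cs$token_start[sel]]),
      char_end = as.integer(tokens$end[cs$token_end[sel]]),
      negated = rep(FALSE, length(sel))
    ),
    nrow = length(sel)
  )
}

#' Flag negated mentions
#'
#' A mention is negated iff a forward trigger occurs within `scope` tokens
#' before its start, or a backward trigger within `scope` tokens after its
#' end, in the same sentence and with no scope-breaker between trigger and
#' mention. Mentions whose matched term begins with a negation token are
#' exempt and never flagged.
#'
#' @param tokens Token tibble for the note.
#' @param mentions Mention tibble from [find_mentions()].
#' @param config Negation configuration from [negation_config()].
#' @return The mention tibble with the `negated` column filled in.
#' @export
detect_negation <- function(tokens, mentions, config = negation_config()) {
  if (nrow(mentions) == 0) return(mentions)
  toks <- tokens$token
  sent <- tokens$sent_id
  scope <- config$scope
  breakers <- config$scope_breakers
  all_triggers <- unique(c(config$forward, config$backward))

  first_tok <- vapply(strsplit(mentions$term, " ", fixed = TRUE),
                      `[`, character(1), 1)
  exempt <- first_tok %in% all_triggers

  negated <- logical(nrow(mentions))
  for (i in seq_len(nrow(mentions))) {
    if (exempt[i]) next
    s <- mentions$token_start[i]
    e <- mentions$token_end[i]
    # forward: trigger before the mention start
    lo <- max(1L, s - scope)
    if (lo <= s - 1L) {
      win <- lo:(s - 1L)
      hit <- win[toks[win] %in% config$forward & sent[win] == sent[s]]
      for (p in hit) {
        between <- if (p + 1L <= s - 1L) (p + 1L):(s - 1L) else integer()
        if (!any(toks[between] %in% breakers)) {
          negated[i] <- TRUE
          break
        }
      }
    }
    if (negated[i]) next
    # backward: trigger after the mention end
    hi <- min(length(toks), e + scope)
    if (e + 1L <= hi) {
      win <- (e + 1L):hi
      hit <- win[toks[win] %in% config$backward & sent[win] == sent[e]]
      for (p in hit) {
        between <- if (e + 1L <= p - 1L) (e + 1L):(p - 1L) else integer()
        if (!any(toks[between] %in% breakers)) {
          negated[i] <- TRUE
          break
        }
      }
    }
  }
  mentions$negated <- negated
  mentions
}

#' Annotate a single note
#'
#' Tokenizes, finds lexicon mentions, applies negation. A subcategory is
#' "present" in the note when it has at least one non-negated mention;
#' negated mentions are retained in the output for audit.
#'
#' @param note One-row notes tibble (or any list with `note_id` and `text`).
#' @param lexicon A lexicon tibble.
#' @param stopwords Stopword list (must match the lexicon's normalization).
#' @param negation Negation configuration.
#' @return A mention tibble with a leading `note_id` column.
#' @export
annotate_note <- function(note, lexicon, stopwords = default_stopwords(),
                          negation = negation_config()) {
  tokens <- tokenize_text(note$text[[1]], stopwords)
  m <- find_mentions(tokens, lexicon)
  m <- detect_negation(tokens, m, negation)
  dplyr::bind_cols(tibble(note_id = rep(note$note_id[[1]], nrow(m))), m)
}

#' Annotate a corpus of notes
#'
#' Applies [annotate_note()] to every note and computes a corpus summary:
#' the fraction of notes containing at least one (non-negated) subcategory
#' mention, overall and broken down by note category.
#'
#' @param notes Notes tibble (`note_id`, `category`, `text`, ...).
#' @param lexicon A lexicon tibble.
#' @param stopwords Stopword list.
#' @param negation Negation configuration.
#' @return A list of class `ineads_annotations` with elements
#'   `annotations` (stacked mention tibble), `note_subcategories`
#'   (distinct non-negated `note_id` x `subcategory` pairs), and `summary`
#'   (list with `n_notes`, `n_notes_with_subcategory`, `fraction`,
#'   `by_category` tibble).
#' @export
annotate_corpus <- function(notes, lexicon, stopwords = default_stopwords(),
                            negation = negation_config()) {
  idx <- lexicon_index(lexicon)
  class(idx) <- c("ineads_lexicon_index", class(idx))
  ann <- purrr::map(seq_len(nrow(notes)), function(i) {
    tokens <- tokenize_text(notes$text[[i]], stopwords)
    m <- find_mentions(tokens, idx)
    if (nrow(m) == 0) return(NULL)
    m <- detect_negation(tokens, m, negation)
    m$note_id <- notes$note_id[[i]]
    m
  }) %>% bind_rows()
  if (nrow(ann) == 0) {
    ann <- tibble(
      note_id = character(), subcategory = character(), term = character(),
      token_start = integer(), token_end = integer(),
      char_start = integer(), char_end = integer(), negated = logical()
    )
  } else {
    ann <- ann[, c("note_id", "subcategory", "term", "token_start",
                   "token_end", "char_start", "char_end", "negated")]
  }
  present <- note_subcategories(ann)
  with_sub <- unique(present$note_id)
  by_cat <- if ("category" %in% names(notes) && nrow(notes) > 0) {
    notes %>%
      mutate(has_subcategory = .data$note_id %in% with_sub) %>%
      group_by(.data$category) %>%
      summarise(n_notes = n(), n_with_subcategory = sum(.data$has_subcategory),
                .groups = "drop") %>%
      mutate(fraction = if_else(.data$n_notes > 0,
                                .data$n_with_subcategory / .data$n_notes, 0))
  } else {
    tibble(category = character(), n_notes = integer(),
           n_with_subcategory = integer(), fraction = double())
  }
  structure(
    list(
      annotations = ann,
      note_subcategories = present,
      summary = list(
        n_notes = nrow(notes),
        n_notes_with_subcategory = length(with_sub),
        fraction = if (nrow(notes) > 0) length(with_sub) / nrow(notes) else 0,
        by_category = by_cat
      )
    ),
    class = "ineads_annotations"
  )
}

#' @export
print.ineads_annotations <- function(x, ...) {
  s <- x$summary
  cat("<ineads annotations> ", nrow(x$annotations), " mentions in ",
      s$n_notes_with_subcategory, "/", s$n_notes, " notes (",
      sprintf("%.1f%%", 100 * s$fraction), " with >=1 subcategory)\n",
      sep = "")
  invisible(x)
}

#' Note-level subcategory presence
#'
#' @param annotations A mention tibble (with `negated`), or an
#'   `ineads_annotations` object.
#' @return Distinct (`note_id`, `subcategory`) pairs with at least one
#'   non-negated mention.
#' @export
note_subcategories <- function(annotations) {
  if (inherits(annotations, "ineads_annotations")) {
    annotations <- annotations$annotations
  }
  annotations %>%
    filter(!.data$negated) %>%
    distinct(.data$note_id, .data$subcategory)
}

#' Write annotations as a flat TSV
#'
#' @param annotations An `ineads_annotations` object or mention tibble.
#' @param path Output TSV path.
#' @return The input, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  ann <- if (inherits(annotations, "ineads_annotations")) {
    annotations$annotations
  } else {
    annotations
  }
  readr::write_tsv(ann, path)
  invisible(annotations)
}
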