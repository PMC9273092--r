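# Reading, filtering and tokenizing clinical note and admission tables.
#
# The expected input schema follows the de-identified critical-care note-events
# convention: one CSV of notes (id, patient, admission, category, chart time,
# free text) and one CSV of admissions (demographics plus in-hospital and
# follow-up death flags).

#' Sentinel token substituted for de-identification placeholders
#'
#' Spans of the form `[** ... **]` (the convention used by de-identified
#' critical-care corpora for names, dates and locations) are replaced by this
#' single token during preprocessing so that placeholder content can never
#' produce a lexicon match.
#'
#' @return A single string.
#' @export
deid_sentinel <- function() "xxphixx"

#' Default stopword list
#'
#' A small set of English function words removed during tokenization. The
#' list deliberately excludes every token that carries clinical meaning for
#' negation or for lexicon terms: "no", "not", "never", "denies", "but",
#' "with", "will" (as in "no living will") and similar tokens are never
#' stopwords.
#'
#' @return Character vector of lowercase stopwords.
#' @export
default_stopwords <- function() {
  c(
    "the", "is", "a", "an", "and", "or", "of", "to", "in", "on", "at",
    "by", "for", "as", "was", "were", "are", "be", "been", "am", "it",
    "its", "this", "that", "these", "those"
  )
}

#' Default note-category inclusion list
#'
#' Note categories likely to document social context, advance directives or
#' decisional capacity. Categories such as radiology, pharmacy and
#' echocardiogram are excluded by default because they rarely carry this
#' information.
#'
#' @return Character vector of normalized (lowercase) category names.
#' @export
default_note_categories <- function() {
  c(
    "case management", "consultation", "discharge summary", "nursing",
    "nutrition", "physician", "rehabilitation", "respiratory",
    "social work", "general"
  )
}

#' Default column mappings for note and admission CSV files
#'
#' Input headers default to the note-events convention (`ROW_ID`,
#' `SUBJECT_ID`, `HADM_ID`, `CATEGORY`, `CHARTTIME`, `TEXT`); supply a named
#' character vector to remap (names are internal fields, values are CSV
#' headers).
#'
#' @return Named character vector mapping internal field names to CSV headers.
#' @export
note_columns <- function() {
  c(
    note_id = "ROW_ID", patient_id = "SUBJECT_ID", admission_id = "HADM_ID",
    category = "CATEGORY", chart_time = "CHARTTIME", text = "TEXT"
  )
}

#' @rdname note_columns
#' @export
admission_columns <- function() {
  c(
    admission_id = "HADM_ID", patient_id = "SUBJECT_ID", age = "AGE",
    gender = "GENDER", ethnicity = "ETHNICITY",
    admission_type = "ADMISSION_TYPE", insurance = "INSURANCE",
    expired_in_hospital = "HOSPITAL_EXPIRE_FLAG",
    expired_in_followup = "EXPIRE_FLAG"
  )
}

normalize_category <- function(x) stringr::str_squish(stringr::str_to_lower(x))

#' Read a clinical-notes CSV
#'
#' Reads a notes table, normalizes note categories to lowercase, and keeps
#' only notes in the configured category inclusion list. The count of
#' excluded rows is reported via a message.
#'
#' @param path Path to a CSV file (comma-separated, quoted multiline text
#'   fields, UTF-8).
#' @param included_categories Character vector of categories to keep
#'   (case-insensitive). Defaults to [default_note_categories()].
#' @param columns Named vector mapping internal fields to CSV headers; see
#'   [note_columns()].
#' @param known_categories Categories that are recognized even though
#'   excluded (e.g. "radiology"). A category outside both sets is treated as
#'   unknown.
#' @param unknown_category What to do with rows whose category is unknown:
#'   `"drop"` (default, with a warning) or `"error"`.
#' @return A tibble with columns `note_id`, `patient_id`, `admission_id`,
#'   `category`, `chart_time`, `text`, in input row order.
#' @export
read_notes <- function(path,
                       included_categories = default_note_categories(),
                       columns = note_columns(),
                       known_categories = c(
                         default_note_categories(),
                         "radiology", "pharmacy", "echocardiogram", "ecg"
                       ),
                       unknown_category = c("drop", "error")) {
  unknown_category <- arg_match(unknown_category)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(paste0("malformed notes CSV at row(s): ",
                 paste(unique(probs$row), collapse = ", ")))
  }
  missing_cols <- setdiff(unname(columns), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("notes CSV is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  notes <- tibble(
    note_id = raw[[columns[["note_id"]]]],
    patient_id = raw[[columns[["patient_id"]]]],
    admission_id = raw[[columns[["admission_id"]]]],
    category = normalize_category(raw[[columns[["category"]]]]),
    chart_time = raw[[columns[["chart_time"]]]],
    text = dplyr::coalesce(raw[[columns[["text"]]]], "")
  )
  if (anyDuplicated(notes$note_id)) abort("duplicate note_id in notes CSV")

  included <- normalize_category(included_categories)
  known <- union(normalize_category(known_categories), included)
  unknown <- !(notes$category %in% known)
  if (any(unknown)) {
    msg <- paste0(sum(unknown), " note(s) with unknown category: ",
                  paste(unique(notes$category[unknown]), collapse = ", "))
    if (unknown_category == "error") abort(msg)
    warn(paste0(msg, " (dropped)"))
  }
  keep <- notes$category %in% included
  inform(paste0("read_notes: kept ", sum(keep), " of ", nrow(notes),
                " notes (", sum(!keep), " excluded by category)"))
  notes[keep, , drop = FALSE]
}

as_flag <- function(x) {
  if (is.logical(x)) return(x)
  x <- stringr::str_to_lower(as.character(x))
  out <- x %in% c("1", "true", "t", "yes", "y")
  out[is.na(x)] <- NA
  out
}

#' Read an admissions CSV
#'
#' Reads the admissions/demographics table and applies the adult-age filter.
#'
#' @param path Path to a CSV file.
#' @param min_age Minimum age in years; admissions younger than this are
#'   excluded (default 18, i.e. adults only).
#' @param columns Named vector mapping internal fields to CSV headers; see
#'   [admission_columns()].
#' @return A tibble with columns `admission_id`, `patient_id`, `age`,
#'   `gender`, `ethnicity`, `admission_type`, `insurance`,
#'   `expired_in_hospital`, `expired_in_followup`.
#' @export
read_admissions <- function(path, min_age = 18, columns = admission_columns()) {
  stopifnot(is.numeric(min_age), min_age >= 0)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(paste0("malformed admissions CSV at row(s): ",
                 paste(unique(probs$row), collapse = ", ")))
  }
  missing_cols <- setdiff(unname(columns), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("admissions CSV is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  adm <- tibble(
    admission_id = raw[[columns[["admission_id"]]]],
    patient_id = raw[[columns[["patient_id"]]]],
    age = as.numeric(raw[[columns[["age"]]]]),
    gender = normalize_category(raw[[columns[["gender"]]]]),
    ethnicity = normalize_category(raw[[columns[["ethnicity"]]]]),
    admission_type = normalize_category(raw[[columns[["admission_type"]]]]),
    insurance = normalize_category(raw[[columns[["insurance"]]]]),
    expired_in_hospital = as_flag(raw[[columns[["expired_in_hospital"]]]]),
    expired_in_followup = as_flag(raw[[columns[["expired_in_followup"]]]])
  )
  validate_admissions(adm)
  adm[!is.na(adm$age) & adm$age >= min_age, , drop = FALSE]
}

validate_admissions <- function(adm) {
  if (anyDuplicated(adm$admission_id)) abort("duplicate admission_id in admissions table")
  if (any(adm$age < 0, na.rm = TRUE)) abort("negative age in admissions table")
  bad <- adm$expired_in_hospital & !adm$expired_in_followup
  if (any(bad, na.rm = TRUE)) {
    abort(paste0("inconsistent death flags (expired in hospital but not in ",
                 "follow-up) for admission(s): ",
                 paste(adm$admission_id[which(bad)], collapse = ", ")))
  }
  invisible(adm)
}

#' Write note and admission tables back to CSV
#'
#' Inverse of [read_notes()] / [read_admissions()]: writes with the header
#' names given by the column mapping so that a written table re-reads to
#' identical field values.
#'
#' @param notes,admissions Tibbles as returned by the readers (or the
#'   synthetic generator).
#' @param path Output CSV path.
#' @param columns Column mapping, as for the readers.
#' @return The input, invisibly.
#' @export
write_notes <- function(notes, path, columns = note_columns()) {
  out <- notes[names(columns)]
  names(out) <- unname(columns)
  readr::write_csv(out, path, na = "")
  invisible(notes)
}

#' @rdname write_notes
#' @export
write_admissions <- function(admissions, path, columns = admission_columns()) {
  out <- admissions[names(columns)]
  out$expired_in_hospital <- as.integer(out$expired_in_hospital)
  out$expired_in_followup <- as.integer(out$expired_in_followup)
  names(out) <- unname(columns)
  readr::write_csv(out, path, na = "")
  invisible(admissions)
}

token_pattern <- function() "[\\p{L}\\p{N}]+(?:-[\\p{L}\\p{N}]+)*"
deid_pattern <- function() "\\[\\*\\*.*?\\*\\*\\]"

#' Tokenize a single free-text string
#'
#' Lowercases, strips punctuation, removes stopwords, and replaces
#' de-identification placeholders (`[** ... **]`) with the sentinel token.
#' Tokens are maximal runs of letters/digits; intra-word hyphens are kept,
#' slashes split ("dnr/dni" yields "dnr", "dni"). Sentence ids are assigned
#' from `.`/`!`/`?`/`;`/newline boundaries in the raw text so that
#' downstream negation scoping can stop at sentence breaks.
#'
#' @param text A single character string (may be empty or `NA`).
#' @param stopwords Character vector of tokens to drop.
#' @return A tibble with columns `token`, `start`, `end` (1-based inclusive
#'   character span into `text`), and `sent_id`. Zero rows for empty text.
#' @export
tokenize_text <- function(text, stopwords = default_stopwords()) {
  empty <- tibble::new_tibble(list(token = character(), start = integer(),
                                   end = integer(), sent_id = integer()),
                              nrow = 0L)
  if (length(text) != 1 || is.na(text) || !nzchar(text)) return(empty)

  deid <- stringr::str_locate_all(text, deid_pattern())[[1]]
  masked <- text
  if (nrow(deid) > 0) {
    for (i in seq_len(nrow(deid))) {
      stringr::str_sub(masked, deid[i, 1], deid[i, 2]) <-
        strrep(" ", deid[i, 2] - deid[i, 1] + 1)
    }
  }
  loc <- stringr::str_locate_all(masked, stringr::regex(token_pattern()))[[1]]
  tok <- if (nrow(loc) > 0) {
    stringr::str_to_lower(stringr::str_sub(text, loc[, 1], loc[, 2]))
  } else {
    character()
  }
  start <- as.integer(loc[, 1])
  end <- as.integer(loc[, 2])
  if (nrow(deid) > 0) {
    tok <- c(tok, rep(deid_sentinel(), nrow(deid)))
    start <- c(start, as.integer(deid[, 1]))
    end <- c(end, as.integer(deid[, 2]))
  }
  ord <- order(start)
  keep <- !(tok[ord] %in% stopwords)
  tok <- tok[ord][keep]
  start <- start[ord][keep]
  end <- end[ord][keep]

  bounds <- stringr::str_locate_all(text, "[.!?;\\n]")[[1]][, 1]
  tibble::new_tibble(
    list(token = tok, start = start, end = end,
         sent_id = findInterval(start, bounds) + 1L),
    nrow = length(tok)
  )
}

#' Tokenize a collection of notes
#'
#' Applies [tokenize_text()] to each note and stacks the results with a
#' per-note token position index.
#'
#' @param notes A notes tibble with `note_id` and `text` columns.
#' @param stopwords Character vector of tokens to drop.
#' @return A tibble with columns `note_id`, `pos` (1-based token position
#'   within the note), `token`, `start`, `end`, `sent_id`.
#' @export
tokenize_notes <- function(notes, stopwords = default_stopwords()) {
  out <- purrr::map2(notes$note_id, notes$text, function(id, txt) {
    tk <- tokenize_text(txt, stopwords)
    if (nrow(tk) == 0) return(NULL)
    tk$note_id <- id
    tk$pos <- seq_len(nrow(tk))
    tk
  })
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(note_id = character(), pos = integer(), token = character(),
                  start = integer(), end = integer(), sent_id = integer()))
  }
  res[, c("note_id", "pos", "token", "start", "end", "sent_id")]
}

#' Reassemble tokens into a plain-text string
#'
#' @param tokens A token tibble as returned by [tokenize_text()].
#' @return A single space-joined string.
#' @export
detokenize <- function(tokens) paste(tokens$token, collapse = " ")
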