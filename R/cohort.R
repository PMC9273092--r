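# Admission-level aggregation and the INEADS cohort rules:
#   possibility      — admission documents >=1 of the five social elevated
#                      subcategories;
#   high_likelihood  — admission documents >=4 of the five;
# the high-likelihood cohort is bifurcated by whether any reduced-potential
# subcategory is also documented.

#' Aggregate note annotations to admission profiles
#'
#' Takes the union of (non-negated) subcategories over all of an
#' admission's notes. Admissions passed in `admissions` but having no
#' annotated notes get an empty profile.
#'
#' @param annotations An `ineads_annotations` object, or a tibble of
#'   note-level mentions, or distinct (`note_id`, `subcategory`) pairs.
#' @param notes Notes tibble linking `note_id` to `admission_id`.
#' @param admissions Optional admissions tibble; when given, every
#'   `admission_id` in it appears in the output.
#' @return A tibble with one row per admission: `admission_id`,
#'   `subcategories` (list column of character vectors), `n_subcategories`,
#'   `n_social_elevated` (0-5), `has_reduced`.
#' @export
aggregate_admissions <- function(annotations, notes, admissions = NULL) {
  present <- if (inherits(annotations, "ineads_annotations")) {
    annotations$note_subcategories
  } else if ("negated" %in% names(annotations)) {
    note_subcategories(annotations)
  } else {
    distinct(annotations, .data$note_id, .data$subcategory)
  }
  unknown <- setdiff(present$note_id, notes$note_id)
  if (length(unknown) > 0) {
    abort(paste0("annotated note(s) missing from the notes table: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  social <- social_elevated_subcategories()
  reduced <- reduced_subcategories()
  by_adm <- present %>%
    left_join(notes[, c("note_id", "admission_id")], by = "note_id") %>%
    distinct(.data$admission_id, .data$subcategory) %>%
    group_by(.data$admission_id) %>%
    summarise(subcategories = list(sort(.data$subcategory)), .groups = "drop")
  if (!is.null(admissions)) {
    all_ids <- tibble(admission_id = unique(admissions$admission_id))
    by_adm <- all_ids %>%
      left_join(by_adm, by = "admission_id") %>%
      mutate(subcategories = purrr::map(.data$subcategories,
                                        ~ if (is.null(.x)) character() else .x))
  }
  by_adm %>%
    mutate(
      n_subcategories = lengths(.data$subcategories),
      n_social_elevated = vapply(.data$subcategories,
                                 function(s) sum(s %in% social), integer(1)),
      has_reduced = vapply(.data$subcategories,
                           function(s) any(s %in% reduced), logical(1))
    )
}

#' Classify admission profiles into INEADS cohorts
#'
#' Applies the cohort rules: `possibility` iff at least one of the five
#' social elevated subcategories is documented, `high_likelihood` iff at
#' least four are, `none` otherwise. High-likelihood admissions are
#' bifurcated by whether any reduced-potential subcategory is also present.
#'
#' @param profiles Profile tibble from [aggregate_admissions()] (needs
#'   `n_social_elevated` and `has_reduced`).
#' @param possibility_min,high_min Rule thresholds (defaults 1 and 4 of the
#'   social five).
#' @return The input with `label` (ordered factor
#'   `none < possibility < high_likelihood`) and `bifurcation`
#'   (`"no_reduced_signal"` / `"has_reduced_signal"`, `NA` outside the
#'   high-likelihood cohort).
#' @export
classify_ineads <- function(profiles, possibility_min = 1, high_min = 4) {
  lab <- dplyr::case_when(
    profiles$n_social_elevated >= high_min ~ "high_likelihood",
    profiles$n_social_elevated >= possibility_min ~ "possibility",
    TRUE ~ "none"
  )
  profiles$label <- factor(lab, levels = c("none", "possibility", "high_likelihood"),
                           ordered = TRUE)
  profiles$bifurcation <- if_else(
    profiles$label == "high_likelihood",
    if_else(profiles$has_reduced, "has_reduced_signal", "no_reduced_signal"),
    NA_character_
  )
  profiles
}

cohort_members <- function(classified, cohort) {
  switch(cohort,
    full = classified$admission_id,
    possibility = classified$admission_id[classified$label >= "possibility"],
    high_likelihood = classified$admission_id[classified$label == "high_likelihood"],
    abort(paste0("unknown cohort: ", cohort))
  )
}

pct <- function(num, den, digits = 0) {
  if (den == 0) return(NA_real_)
  round(100 * num / den, digits)
}

categorical_characteristics <- function() {
  c("gender", "ethnicity", "admission_type", "insurance")
}

#' Summarize cohort characteristics
#'
#' Builds a long, table-style summary of the full, possibility and
#' high-likelihood cohorts: cohort sizes (with percent of all admissions),
#' follow-up and in-hospital mortality n (%), mean (SD) age, and n (%) for
#' each categorical characteristic.
#'
#' @param admissions Admissions tibble.
#' @param classified Classified profile tibble from [classify_ineads()].
#' @param cohorts Cohorts to summarize.
#' @return A tibble of class `ineads_cohort_summary` with columns `cohort`,
#'   `characteristic`, `level`, `n`, `pct`, `mean`, `sd` (the last two only
#'   for age rows).
#' @export
summarize_cohorts <- function(admissions, classified,
                              cohorts = c("full", "possibility", "high_likelihood")) {
  missing_ids <- setdiff(admissions$admission_id, classified$admission_id)
  if (length(missing_ids) > 0) {
    abort(paste0("profiles missing for ", length(missing_ids), " admission(s)"))
  }
  n_all <- nrow(admissions)
  rows <- purrr::map(cohorts, function(ch) {
    ids <- cohort_members(classified, ch)
    sub <- admissions[admissions$admission_id %in% ids, , drop = FALSE]
    n_ch <- nrow(sub)
    out <- list(tibble(
      cohort = ch, characteristic = "n", level = "admissions",
      n = n_ch, pct = pct(n_ch, n_all, 1), mean = NA_real_, sd = NA_real_
    ))
    if (n_ch == 0) return(bind_rows(out))
    out <- c(out, list(
      tibble(cohort = ch, characteristic = "expired_in_followup", level = "yes",
             n = sum(sub$expired_in_followup, na.rm = TRUE),
             pct = pct(sum(sub$expired_in_followup, na.rm = TRUE), n_ch),
             mean = NA_real_, sd = NA_real_),
      tibble(cohort = ch, characteristic = "expired_in_hospital", level = "yes",
             n = sum(sub$expired_in_hospital, na.rm = TRUE),
             pct = pct(sum(sub$expired_in_hospital, na.rm = TRUE), n_ch),
             mean = NA_real_, sd = NA_real_),
      tibble(cohort = ch, characteristic = "age", level = "years",
             n = n_ch, pct = NA_real_,
             mean = round(mean(sub$age, na.rm = TRUE)),
             sd = round(stats::sd(sub$age, na.rm = TRUE)))
    ))
    for (char in categorical_characteristics()) {
      tab <- sub %>%
        count(level = .data[[char]]) %>%
        mutate(cohort = ch, characteristic = char,
               pct = vapply(n, pct, numeric(1), den = n_ch),
               mean = NA_real_, sd = NA_real_) %>%
        select("cohort", "characteristic", "level", "n", "pct", "mean", "sd")
      out <- c(out, list(tab))
    }
    bind_rows(out)
  })
  res <- bind_rows(rows)
  class(res) <- c("ineads_cohort_summary", class(res))
  res
}

#' Compare a cohort's characteristics against the full cohort
#'
#' Welch two-sample t-test for age; chi-square tests (no continuity
#' correction) on full-vs-subcohort contingency tables for categorical
#' characteristics and the mortality flags. Following the source protocol
#' the subcohort is compared against the *full* cohort (which contains it);
#' the resulting non-independence is a documented caveat, not corrected for.
#'
#' @param admissions Admissions tibble.
#' @param classified Classified profiles from [classify_ineads()].
#' @param cohort `"possibility"` or `"high_likelihood"`.
#' @return A tibble with `characteristic`, `test`, `statistic`, `df`,
#'   `p_value`, `sig_05`, `sig_001`.
#' @export
compare_cohorts <- function(admissions, classified,
                            cohort = c("possibility", "high_likelihood")) {
  cohort <- arg_match(cohort)
  ids <- cohort_members(classified, cohort)
  sub <- admissions[admissions$admission_id %in% ids, , drop = FALSE]
  if (nrow(sub) == 0) abort(paste0("empty cohort: ", cohort))

  res <- list()
  tt <- t.test(admissions$age, sub$age)
  res[[1]] <- tibble(characteristic = "age", test = "welch_t",
                     statistic = unname(tt$statistic), df = unname(tt$parameter),
                     p_value = tt$p.value)
  chisq_row <- function(char, full_counts, sub_counts) {
    tab <- rbind(full = full_counts, sub = sub_counts)
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (ncol(tab) < 2) {
      return(tibble(characteristic = char, test = "chi_square",
                    statistic = NA_real_, df = NA_real_, p_value = NA_real_))
    }
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    if (any(ct$expected == 0)) {
      abort(paste0("zero expected counts in chi-square for ", char))
    }
    tibble(characteristic = char, test = "chi_square",
           statistic = unname(ct$statistic), df = unname(ct$parameter),
           p_value = ct$p.value)
  }
  for (char in c("expired_in_followup", "expired_in_hospital")) {
    f <- table(factor(admissions[[char]], levels = c(FALSE, TRUE)))
    s <- table(factor(sub[[char]], levels = c(FALSE, TRUE)))
    res[[length(res) + 1]] <- chisq_row(char, as.integer(f), as.integer(s))
  }
  for (char in categorical_characteristics()) {
    lev <- sort(unique(admissions[[char]]))
    f <- table(factor(admissions[[char]], levels = lev))
    s <- table(factor(sub[[char]], levels = lev))
    res[[length(res) + 1]] <- chisq_row(char, as.integer(f), as.integer(s))
  }
  bind_rows(res) %>%
    mutate(sig_05 = .data$p_value < 0.05, sig_001 = .data$p_value < 0.001)
}

#' Default qualifying diagnosis-code patterns
#'
#' Regular expressions selecting admissions whose diagnoses could be
#' associated with lacking surrogates or directives: psychiatric disorders,
#' tuberculosis, hepatitis C, and HIV/AIDS. Both ICD-9 and ICD-10 style
#' patterns are shipped because source datasets differ in coding system;
#' the list is configuration, not a claim about any particular dataset.
#'
#' @return Character vector of regular expressions matched against
#'   diagnosis codes.
#' @export
default_qualifying_codes <- function() {
  c(
    "^29[0-9]", "^30[0-9]", "^31[0-9]", # ICD-9 mental disorders 290-319
    "^01[0-8]",                         # ICD-9 tuberculosis
    "^070\\.?(41|44|51|54|70|71)",      # ICD-9 hepatitis C
    "^042",                             # ICD-9 HIV
    "^F[0-9]",                          # ICD-10 mental/behavioural
    "^A1[5-9]",                         # ICD-10 tuberculosis
    "^B17\\.?1", "^B18\\.?2",           # ICD-10 hepatitis C
    "^B2[0-4]", "^Z21"                  # ICD-10 HIV
  )
}

#' Sample a gold-standard note set
#'
#' Restricts to notes of admissions carrying at least one qualifying
#' diagnosis code, then samples `n` notes uniformly without replacement,
#' reproducibly for a fixed seed.
#'
#' @param notes Notes tibble.
#' @param diagnoses Tibble with `admission_id` and `code`.
#' @param n Sample size.
#' @param seed Integer seed.
#' @param qualifying_codes Regex patterns; see [default_qualifying_codes()].
#' @return A tibble of `n` sampled notes (subset of `notes`).
#' @export
sample_gold_standard <- function(notes, diagnoses, n, seed,
                                 qualifying_codes = default_qualifying_codes()) {
  pat <- paste0("(", paste(qualifying_codes, collapse = ")|("), ")")
  qualifying <- unique(diagnoses$admission_id[
    stringr::str_detect(diagnoses$code, pat)
  ])
  pool <- notes[notes$admission_id %in% qualifying, , drop = FALSE]
  if (nrow(pool) == 0) abort("no notes belong to admissions with qualifying codes")
  if (n > nrow(pool)) {
    abort(paste0("requested sample of ", n, " exceeds eligible pool of ",
                 nrow(pool), " notes"))
  }
  picked <- withr::with_seed(seed, sample(pool$note_id, n))
  pool[match(picked, pool$note_id), , drop = FALSE]
}

#' Write admission profiles as TSV
#'
#' @param classified Classified profile tibble.
#' @param path Output path.
#' @return The input, invisibly.
#' @export
write_profiles <- function(classified, path) {
  out <- classified %>%
    mutate(subcategories = vapply(.data$subcategories, paste,
                                  character(1), collapse = ";"),
           label = as.character(.data$label))
  readr::write_tsv(out, path)
  invisible(classified)
}
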