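# Synthetic corpus generator with known ground truth. Notes are telegraphic
# template sentences in the style of de-identified critical-care notes:
# planted subcategory terms, optional negation wrappers, optional held-out
# synonym substitution, distractor filler, de-identification placeholders.
# Every plant is recorded, so gold note labels and admission profiles are
# exact by construction.

#' Note templates for each subcategory
#'
#' Five hand-written telegraphic sentence templates per subcategory, each
#' with a `{term}` slot, shipped as a data file
#' (`inst/extdata/templates.tsv`) so users can extend them. Scaffolds
#' deliberately avoid lexicon vocabulary and negation triggers around the
#' slot, and the words adjacent to the slot are reused across all
#' subcategories: in real notes the words framing a social-history fact
#' recur in many contexts, and this shared framing is what lets collocation
#' detection keep a planted term as its own token instead of fusing it into
#' its scaffold.
#'
#' @return A tibble with columns `subcategory`, `template`.
#' @export
ineads_templates <- function() {
  path <- system.file("extdata", "templates.tsv", package = "ineads",
                      mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
}

# Negation wrappers applied to a rendered plant sentence when a
# reduced-potential mention is negated; {term} slot as in templates.
negation_wrappers <- function() {
  c(
    "pt denies {term}",
    "denies {term} per interview",
    "no {term} at this time",
    "not {term} per report",
    "pt without {term} currently"
  )
}

#' Distractor sentence pool
#'
#' Clinical filler sentences containing no lexicon term, so they can never
#' produce a mention; two include de-identification placeholders.
#'
#' @return Character vector of sentences.
#' @export
distractor_sentences <- function() {
  c(
    "vital signs stable overnight",
    "lungs clear bilaterally no wheezes",
    "continue current medications as ordered",
    "plan physical therapy this week",
    "abdomen soft nontender bowel sounds present",
    "skin intact no breakdown noted",
    "tolerating diet well",
    "afebrile hemodynamically stable",
    "foley draining clear yellow urine",
    "will follow up labs in am",
    "pain controlled with current regimen",
    "encourage incentive spirometry",
    "telemetry without ectopy overnight",
    "sbp ranging 110s to 130s",
    "repeat cxr in the morning",
    "neuro checks q4h unchanged",
    "[**Name**] rn signed note",
    "seen by [**First Name**] this am"
  )
}

#' Held-out synonym table
#'
#' One unseen synonym per subcategory, absent from the seed lexicon. The
#' generator can substitute these for seed terms (carrying the same gold
#' subcategory), which makes lexicon-expansion recall measurable: the
#' baseline lexicon misses them, and embedding-driven expansion should
#' recover them.
#'
#' @return A tibble with columns `subcategory`, `synonym`.
#' @export
held_out_synonyms <- function() {
  tibble::tribble(
    ~subcategory, ~synonym,
    "married", "wedded",
    "partnered", "longtime companion",
    "relatives_unknown_involvement", "stepdaughter",
    "caregiver_support", "caretaker",
    "living_with_others", "cohabitating",
    "community_connection", "neighborhood circle",
    "religious_connections", "parish priest",
    "surrogate_identified", "designated spokesperson",
    "unmarried", "never wed",
    "living_alone", "resides alone",
    "transitionally_situated", "unsheltered",
    "surrogate_unidentified", "kin unreachable",
    "palliative_care", "comfort measures",
    "hospice", "terminal care",
    "advance_directives_available", "proxy paperwork",
    "advance_directives_unavailable", "undocumented wishes",
    "lacking_capacity", "encephalopathic"
  )
}

#' Generator configuration
#'
#' Defaults describe a critical-care-like corpus: telegraphic notes,
#' mostly nursing and physician categories, per-admission subcategory
#' planting probabilities chosen so the well-documented subcategories
#' (relatives, lacking capacity, surrogate identified, directives
#' available) dominate and each of the five social elevated subcategories
#' is planted in about 7% of admissions (so roughly 30% of admissions have
#' at least one), and mortality enriched with the social-elevated count.
#'
#' @param n_admissions Number of admissions.
#' @param mean_notes Mean notes per admission (min 1; Poisson-shifted).
#' @param plant_prob Named probability vector over the 17 subcategories.
#' @param negation_rate Probability that a planted *reduced-potential*
#'   mention is wrapped in a negation (negated plants are excluded from
#'   gold labels). Terms that themselves begin with a negation token are
#'   never wrapped.
#' @param synonym_substitution_rate Probability that a planted term is
#'   replaced by its subcategory's held-out synonym (gold label unchanged).
#' @param mean_distractors Mean distractor sentences per note (min 1).
#' @param demographics List of sampling parameters (age mean/sd and
#'   categorical probability vectors).
#' @param mortality List with `followup_base`, `hospital_base` and
#'   `enrichment` (log-odds increment per social-elevated subcategory,
#'   linking documentation of social isolation to mortality).
#' @param note_categories Named probability vector of note categories.
#' @param seed Integer seed fixing the full corpus.
#' @return A config list of class `ineads_sim_config`.
#' @export
synthetic_config <- function(n_admissions = 1000,
                             mean_notes = 3,
                             plant_prob = NULL,
                             negation_rate = 0,
                             synonym_substitution_rate = 0,
                             mean_distractors = 2,
                             demographics = NULL,
                             mortality = list(followup_base = 0.45,
                                              hospital_base = 0.10,
                                              enrichment = 0.35),
                             note_categories = c(
                               nursing = 0.70, physician = 0.23,
                               "social work" = 0.02, nutrition = 0.01,
                               "case management" = 0.01,
                               "discharge summary" = 0.02, general = 0.01
                             ),
                             seed = 42) {
  if (is.null(plant_prob)) {
    plant_prob <- c(
      married = 0.25, partnered = 0.10, relatives_unknown_involvement = 0.72,
      caregiver_support = 0.08, living_with_others = 0.10,
      community_connection = 0.10, religious_connections = 0.05,
      surrogate_identified = 0.41, unmarried = 0.07, living_alone = 0.07,
      transitionally_situated = 0.07, surrogate_unidentified = 0.07,
      palliative_care = 0.06, hospice = 0.03,
      advance_directives_available = 0.36,
      advance_directives_unavailable = 0.07, lacking_capacity = 0.57
    )
  }
  if (is.null(demographics)) {
    demographics <- list(
      age_mean = 60, age_sd = 18,
      gender = c(female = 0.54, male = 0.46),
      ethnicity = c(white = 0.71, black = 0.14, hispanic = 0.04,
                    other = 0.04, unknown = 0.07),
      admission_type = c(elective = 0.12, emergency = 0.86, urgent = 0.02),
      insurance = c(medicaid = 0.14, medicare = 0.59, private = 0.22,
                    "self pay" = 0.01, government = 0.04)
    )
  }
  stopifnot(
    n_admissions >= 1,
    all(plant_prob >= 0 & plant_prob <= 1),
    negation_rate >= 0, negation_rate <= 1,
    synonym_substitution_rate >= 0, synonym_substitution_rate <= 1
  )
  missing_templates <- setdiff(names(plant_prob)[plant_prob > 0],
                               unique(ineads_templates()$subcategory))
  if (length(missing_templates) > 0) {
    abort(paste0("no templates for planted subcategory(ies): ",
                 paste(missing_templates, collapse = ", ")))
  }
  structure(
    list(
      n_admissions = as.integer(n_admissions), mean_notes = mean_notes,
      plant_prob = plant_prob, negation_rate = negation_rate,
      synonym_substitution_rate = synonym_substitution_rate,
      mean_distractors = mean_distractors, demographics = demographics,
      mortality = mortality, note_categories = note_categories,
      seed = as.integer(seed)
    ),
    class = "ineads_sim_config"
  )
}

fill_template <- function(template, term) {
  gsub("{term}", term, template, fixed = TRUE)
}

#' Generate a synthetic corpus with known ground truth
#'
#' For each admission, subcategories are planted independently with the
#' configured probabilities; each plant picks a term from the seed
#' vocabulary and a subcategory template, is optionally negated
#' (reduced-potential plants only) or substituted by a held-out synonym,
#' and is placed in a random note alongside distractor sentences.
#' Demographics are sampled per admission, with death probabilities
#' enriched by the admission's social-elevated count. The whole corpus is a
#' deterministic function of the config seed.
#'
#' @param config An `ineads_sim_config` from [synthetic_config()].
#' @return An object of class `ineads_sim`: list with `notes`,
#'   `admissions` (corpus-schema tibbles), `plants` (full plant ledger:
#'   `note_id`, `admission_id`, `subcategory`, `term`, `negated`,
#'   `substituted`), `gold_notes` (non-negated note labels), `substitutions`,
#'   `held_out_synonyms`, and `config`.
#' @export
generate_corpus <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "ineads_sim_config"))
  templates <- ineads_templates()
  terms <- seed_terms()
  synonyms <- held_out_synonyms()
  schema <- subcategory_schema()
  reduced <- reduced_subcategories()
  triggers <- unique(c(negation_config()$forward, negation_config()$backward))
  distractors <- distractor_sentences()
  subcats <- names(config$plant_prob)
  all_surface <- unique(c(unlist(terms, use.names = FALSE), synonyms$synonym))
  first_tok_map <- vapply(all_surface, function(tm) tokenize_text(tm)$token[1],
                          character(1))

  withr::with_seed(config$seed, {
    note_rows <- list()
    plant_rows <- list()
    adm_rows <- vector("list", config$n_admissions)
    note_counter <- 0L

    for (i in seq_len(config$n_admissions)) {
      adm_id <- sprintf("A%05d", i)
      pat_id <- sprintf("P%05d", i)
      n_notes <- 1L + rpois(1, max(config$mean_notes - 1, 0))
      sentences <- vector("list", n_notes)
      for (j in seq_len(n_notes)) {
        nd <- 1L + rpois(1, max(config$mean_distractors - 1, 0))
        sentences[[j]] <- sample(distractors, min(nd, length(distractors)))
      }
      note_ids <- sprintf("N%07d", note_counter + seq_len(n_notes))
      note_counter <- note_counter + n_notes

      planted <- subcats[runif(length(subcats)) < config$plant_prob]
      np <- length(planted)
      p_note <- character(np)
      p_term <- character(np)
      p_neg <- logical(np)
      p_subst <- logical(np)
      for (pi in seq_along(planted)) {
        sub <- planted[pi]
        term <- sample(terms[[sub]], 1)
        substituted <- FALSE
        if (runif(1) < config$synonym_substitution_rate) {
          syn <- synonyms$synonym[synonyms$subcategory == sub]
          if (length(syn) == 1) {
            term <- syn
            substituted <- TRUE
          }
        }
        negated <- FALSE
        if (sub %in% reduced && config$negation_rate > 0 &&
            !(first_tok_map[[term]] %in% triggers) &&
            runif(1) < config$negation_rate) {
          negated <- TRUE
        }
        sentence <- if (negated) {
          fill_template(sample(negation_wrappers(), 1), term)
        } else {
          pool <- templates$template[templates$subcategory == sub]
          fill_template(sample(pool, 1), term)
        }
        k <- sample.int(n_notes, 1)
        sentences[[k]] <- c(sentences[[k]], sentence)
        p_note[pi] <- note_ids[k]
        p_term[pi] <- term
        p_neg[pi] <- negated
        p_subst[pi] <- substituted
      }
      if (np > 0) {
        plant_rows[[length(plant_rows) + 1L]] <- tibble(
          note_id = p_note, admission_id = adm_id, subcategory = planted,
          term = p_term, negated = p_neg, substituted = p_subst
        )
      }

      cats <- sample(names(config$note_categories), n_notes, replace = TRUE,
                     prob = config$note_categories)
      texts <- vapply(sentences, function(s) {
        paste0(paste(sample(s), collapse = ". "), ".")
      }, character(1))
      note_rows[[length(note_rows) + 1L]] <- tibble(
        note_id = note_ids, patient_id = pat_id, admission_id = adm_id,
        category = cats,
        chart_time = sprintf("2010-%02d-%02d 08:00:00",
                             1L + (i %% 12L), 1L + (seq_len(n_notes) %% 28L)),
        text = texts
      )

      dem <- config$demographics
      n_social <- length(unique(planted[!p_neg &
                                          planted %in% social_elevated_subcategories()]))
      mt <- config$mortality
      p_hosp <- stats::plogis(stats::qlogis(mt$hospital_base) +
                                mt$enrichment * n_social)
      p_follow <- stats::plogis(stats::qlogis(mt$followup_base) +
                                  mt$enrichment * n_social)
      died_hosp <- runif(1) < p_hosp
      died_follow <- died_hosp || runif(1) < p_follow
      adm_rows[[i]] <- tibble(
        admission_id = adm_id, patient_id = pat_id,
        age = max(18, min(99, round(rnorm(1, dem$age_mean, dem$age_sd)))),
        gender = sample(names(dem$gender), 1, prob = dem$gender),
        ethnicity = sample(names(dem$ethnicity), 1, prob = dem$ethnicity),
        admission_type = sample(names(dem$admission_type), 1,
                                prob = dem$admission_type),
        insurance = sample(names(dem$insurance), 1, prob = dem$insurance),
        expired_in_hospital = died_hosp, expired_in_followup = died_follow
      )
    }

    plants <- if (length(plant_rows) > 0) bind_rows(plant_rows) else tibble(
      note_id = character(), admission_id = character(),
      subcategory = character(), term = character(), negated = logical(),
      substituted = logical()
    )
    structure(
      list(
        notes = bind_rows(note_rows),
        admissions = bind_rows(adm_rows),
        plants = plants,
        gold_notes = plants %>% filter(!.data$negated) %>%
          distinct(.data$note_id, .data$subcategory),
        substitutions = plants %>% filter(.data$substituted),
        held_out_synonyms = synonyms,
        config = config
      ),
      class = "ineads_sim"
    )
  })
}

#' @export
print.ineads_sim <- function(x, ...) {
  cat("<ineads synthetic corpus> ", nrow(x$notes), " notes, ",
      nrow(x$admissions), " admissions, ", nrow(x$plants),
      " planted mentions (seed ", x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Substitute held-out synonyms into an existing corpus
#'
#' Each eligible plant (not already substituted, subcategory has a held-out
#' synonym) is replaced in the note text by its synonym with probability
#' `rate`. Gold labels are unchanged: the substitute carries the same
#' subcategory. Every substitution is recorded in the ledger.
#'
#' @param corpus An `ineads_sim` corpus.
#' @param rate Substitution probability in `[0, 1]`.
#' @param seed Integer seed for the substitution draws.
#' @return The corpus with updated `notes`, `plants` and `substitutions`.
#' @export
plant_synonyms <- function(corpus, rate, seed = corpus$config$seed + 1) {
  stopifnot(inherits(corpus, "ineads_sim"), rate >= 0, rate <= 1)
  synonyms <- corpus$held_out_synonyms
  if (nrow(synonyms) == 0) abort("held-out synonym table is empty")
  plants <- corpus$plants
  eligible <- which(!plants$substituted &
                      plants$subcategory %in% synonyms$subcategory)
  withr::with_seed(seed, {
    chosen <- eligible[runif(length(eligible)) < rate]
  })
  notes <- corpus$notes
  for (i in chosen) {
    syn <- synonyms$synonym[synonyms$subcategory == plants$subcategory[i]]
    row <- match(plants$note_id[i], notes$note_id)
    notes$text[row] <- stringr::str_replace(
      notes$text[row], stringr::fixed(plants$term[i]), syn
    )
    plants$term[i] <- syn
    plants$substituted[i] <- TRUE
  }
  corpus$notes <- notes
  corpus$plants <- plants
  corpus$substitutions <- plants %>% filter(.data$substituted)
  corpus
}

#' Expected cohort labels from planted ground truth
#'
#' Applies the admission-aggregation and cohort rules directly to the
#' planted (non-negated) gold labels, bypassing the NLP matcher, for
#' pipeline-level comparison.
#'
#' @param corpus An `ineads_sim` corpus.
#' @return A classified profile tibble (see [classify_ineads()]).
#' @export
end_to_end_truth <- function(corpus) {
  stopifnot(inherits(corpus, "ineads_sim"))
  aggregate_admissions(corpus$gold_notes, corpus$notes, corpus$admissions) %>%
    classify_ineads()
}

#' Write a synthetic corpus to disk
#'
#' Emits the corpus-module CSV schemas plus gold labels and the plant
#' ledger as TSV.
#'
#' @param corpus An `ineads_sim` corpus.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_notes(corpus$notes, file.path(dir, "notes.csv"))
  write_admissions(corpus$admissions, file.path(dir, "admissions.csv"))
  readr::write_tsv(corpus$gold_notes, file.path(dir, "gold_notes.tsv"))
  readr::write_tsv(corpus$plants, file.path(dir, "plants.tsv"))
  invisible(dir)
}
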