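small_config <- function(...) synthetic_config(n_admissions = 60, ...)

test_that("synthetic_config validates rates and template coverage", {
  expect_error(synthetic_config(negation_rate = 1.5))
  expect_error(synthetic_config(synonym_substitution_rate = -0.1))
  expect_error(synthetic_config(n_admissions = 0))
  expect_error(synthetic_config(plant_prob = c(astrology = 0.5)),
               "astrology")
})

test_that("every subcategory ships five templates with a term slot", {
  tpl <- ineads_templates()
  expect_setequal(unique(tpl$subcategory), subcategory_schema()$subcategory)
  counts <- table(tpl$subcategory)
  expect_true(all(counts == 5))
  expect_true(all(grepl("{term}", tpl$template, fixed = TRUE)))
})

test_that("template scaffolds and distractors contain no lexicon term", {
  lx <- seed_default_lexicon()
  scaffolds <- gsub("\\s+", " ",
                    gsub("{term}", "", ineads_templates()$template, fixed = TRUE))
  for (s in c(scaffolds, distractor_sentences())) {
    expect_equal(nrow(find_mentions(tokenize_text(s), lx)), 0)
  }
})

test_that("held-out synonyms are absent from the seed lexicon", {
  lx <- seed_default_lexicon()
  ho <- held_out_synonyms()
  expect_equal(nrow(ho), 17)
  expect_setequal(ho$subcategory, subcategory_schema()$subcategory)
  norm <- vapply(ho$synonym, normalize_term, character(1))
  expect_length(intersect(norm, lx$term), 0)
  # and they are invisible to the seed matcher
  for (syn in ho$synonym) {
    expect_equal(nrow(find_mentions(tokenize_text(syn), lx)), 0)
  }
})

test_that("generate_corpus is reproducible for a fixed seed", {
  c1 <- generate_corpus(small_config(seed = 5))
  c2 <- generate_corpus(small_config(seed = 5))
  c3 <- generate_corpus(small_config(seed = 6))
  expect_identical(c1$notes, c2$notes)
  expect_identical(c1$admissions, c2$admissions)
  expect_identical(c1$plants, c2$plants)
  expect_false(identical(c1$notes$text, c3$notes$text))
})

test_that("the plant ledger is consistent with the emitted tables", {
  sim <- generate_corpus(small_config(seed = 9))
  expect_false(anyDuplicated(sim$notes$note_id) > 0)
  expect_true(all(sim$plants$note_id %in% sim$notes$note_id))
  expect_true(all(sim$plants$admission_id %in% sim$admissions$admission_id))
  # gold labels are exactly the distinct non-negated plants
  manual <- dplyr::distinct(sim$plants[!sim$plants$negated, ],
                            note_id, subcategory)
  expect_equal(dplyr::arrange(sim$gold_notes, note_id, subcategory),
               dplyr::arrange(manual, note_id, subcategory))
  # every planted term literally occurs in its note's text
  joined <- dplyr::left_join(sim$plants, sim$notes, by = "note_id")
  expect_true(all(mapply(grepl, joined$term, joined$text, fixed = TRUE)))
})

test_that("negation wraps only reduced-potential, non-exempt plants", {
  sim <- generate_corpus(small_config(seed = 4, negation_rate = 1))
  neg <- sim$plants[sim$plants$negated, ]
  expect_gt(nrow(neg), 0)
  expect_true(all(neg$subcategory %in% reduced_subcategories()))
  triggers <- unique(c(negation_config()$forward, negation_config()$backward))
  first <- vapply(strsplit(neg$term, " "), `[`, character(1), 1)
  expect_false(any(first %in% triggers))
})

test_that("admissions carry plausible demographics and consistent mortality", {
  sim <- generate_corpus(small_config(seed = 2))
  adm <- sim$admissions
  expect_true(all(adm$age >= 18 & adm$age <= 99))
  expect_true(all(adm$gender %in% c("female", "male")))
  # hospital death implies follow-up death
  expect_true(all(!adm$expired_in_hospital | adm$expired_in_followup))
})

test_that("plant_synonyms substitutes in text and records a ledger", {
  sim <- generate_corpus(small_config(seed = 3))
  sub <- plant_synonyms(sim, rate = 1)
  expect_gt(nrow(sub$substitutions), 0)
  joined <- dplyr::left_join(sub$substitutions, sub$notes, by = "note_id")
  ho <- held_out_synonyms()
  syn_for <- stats::setNames(ho$synonym, ho$subcategory)
  expect_true(all(mapply(grepl, syn_for[joined$subcategory], joined$text,
                         fixed = TRUE)))
})

test_that("end_to_end_truth equals manual aggregation of gold labels", {
  sim <- generate_corpus(small_config(seed = 8))
  truth <- end_to_end_truth(sim)
  manual <- classify_ineads(
    aggregate_admissions(sim$gold_notes, sim$notes, sim$admissions)
  )
  expect_equal(truth, manual)
})

test_that("corpus tables survive a disk round-trip", {
  sim <- generate_corpus(small_config(seed = 12))
  dir <- withr::local_tempdir()
  write_corpus(sim, dir)
  notes <- suppressMessages(suppressWarnings(
    read_notes(file.path(dir, "notes.csv"))
  ))
  adm <- suppressMessages(read_admissions(file.path(dir, "admissions.csv")))
  expect_setequal(notes$note_id,
                  sim$notes$note_id[sim$notes$category %in%
                                      default_note_categories()])
  expect_equal(nrow(adm), nrow(sim$admissions))
})

test_that("recall rises monotonically as held-out synonyms are accepted", {
  sim <- generate_corpus(synthetic_config(n_admissions = 250,
                                          synonym_substitution_rate = 0.5,
                                          seed = 31))
  expect_gt(nrow(sim$substitutions), 0)
  lx0 <- seed_default_lexicon()
  ho <- held_out_synonyms()
  add <- function(base, rows) {
    dplyr::bind_rows(base, tibble::tibble(
      term = vapply(rows$synonym, normalize_term, character(1)),
      subcategory = rows$subcategory, provenance = "accepted_synonym"
    ))
  }
  recall_of <- function(lex) {
    ann <- suppressMessages(annotate_corpus(sim$notes, lex))
    evaluate_annotations(ann$note_subcategories, sim$gold_notes,
                         note_ids = sim$notes$note_id)$overall$recall
  }
  r0 <- recall_of(lx0)
  r50 <- recall_of(add(lx0, ho[1:8, ]))
  r100 <- recall_of(add(lx0, ho))
  expect_lt(r0, r50)
  expect_lt(r50, r100)
  expect_equal(r100, 1)
})
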