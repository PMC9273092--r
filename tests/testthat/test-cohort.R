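make_profiles <- function(sets) {
  social <- social_elevated_subcategories()
  reduced <- reduced_subcategories()
  tibble::tibble(
    admission_id = sprintf("A%03d", seq_along(sets)),
    subcategories = lapply(sets, sort),
    n_subcategories = lengths(sets),
    n_social_elevated = vapply(sets, function(s) sum(s %in% social), integer(1)),
    has_reduced = vapply(sets, function(s) any(s %in% reduced), logical(1))
  )
}

test_that("aggregate_admissions unions note subcategories per admission", {
  notes <- tibble::tibble(
    note_id = c("N1", "N2", "N3"),
    admission_id = c("A1", "A1", "A2")
  )
  pairs <- tibble::tibble(
    note_id = c("N1", "N2", "N2", "N3"),
    subcategory = c("married", "married", "living_alone", "hospice")
  )
  prof <- aggregate_admissions(pairs, notes)
  a1 <- prof$subcategories[[which(prof$admission_id == "A1")]]
  expect_equal(a1, c("living_alone", "married"))
  expect_equal(prof$n_subcategories[prof$admission_id == "A1"], 2)
  expect_true(prof$has_reduced[prof$admission_id == "A1"])
  expect_equal(prof$n_social_elevated[prof$admission_id == "A1"], 1)
})

test_that("admissions without annotated notes get empty profiles", {
  notes <- tibble::tibble(note_id = "N1", admission_id = "A1")
  pairs <- tibble::tibble(note_id = "N1", subcategory = "married")
  adm <- tibble::tibble(admission_id = c("A1", "A2"))
  prof <- aggregate_admissions(pairs, notes, adm)
  expect_equal(nrow(prof), 2)
  expect_equal(prof$n_subcategories[prof$admission_id == "A2"], 0)
  expect_false(prof$has_reduced[prof$admission_id == "A2"])
})

test_that("aggregate_admissions rejects notes missing from the notes table", {
  notes <- tibble::tibble(note_id = "N1", admission_id = "A1")
  pairs <- tibble::tibble(note_id = "N9", subcategory = "married")
  expect_error(aggregate_admissions(pairs, notes), "N9")
})

test_that("cohort rules classify hand-constructed profiles correctly", {
  social <- social_elevated_subcategories()
  cls <- classify_ineads(make_profiles(list(
    character(),                      # nothing documented
    "married",                        # reduced only
    "living_alone",                   # one social elevated
    social[1:3],                      # three of five
    social[1:4],                      # four of five
    c(social, "married")              # all five plus a reduced signal
  )))
  expect_equal(as.character(cls$label),
               c("none", "none", "possibility", "possibility",
                 "high_likelihood", "high_likelihood"))
  expect_equal(cls$bifurcation,
               c(NA, NA, NA, NA, "no_reduced_signal", "has_reduced_signal"))
  expect_s3_class(cls$label, "ordered")
})

test_that("possibility cohort contains the high-likelihood cohort", {
  social <- social_elevated_subcategories()
  cls <- classify_ineads(make_profiles(list(
    character(), social[1], social[1:4], social
  )))
  poss <- cohort_members(cls, "possibility")
  high <- cohort_members(cls, "high_likelihood")
  expect_true(all(high %in% poss))
  expect_equal(cohort_members(cls, "full"), cls$admission_id)
  expect_error(cohort_members(cls, "everyone"), "unknown cohort")
})

make_admissions <- function(n, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    admission_id = sprintf("A%03d", 1:n),
    patient_id = sprintf("P%03d", 1:n),
    age = round(runif(n, 20, 95)),
    gender = sample(c("female", "male"), n, replace = TRUE),
    ethnicity = sample(c("white", "black", "other"), n, replace = TRUE),
    admission_type = sample(c("emergency", "elective"), n, replace = TRUE),
    insurance = sample(c("medicare", "private"), n, replace = TRUE),
    expired_in_hospital = runif(n) < 0.1,
    expired_in_followup = NA
  ) |> dplyr::mutate(
    expired_in_followup = expired_in_hospital | runif(n) < 0.3
  ))
}

test_that("summarize_cohorts reports sizes, mortality, age and categoricals", {
  adm <- make_admissions(60)
  social <- social_elevated_subcategories()
  sets <- withr::with_seed(2, lapply(1:60, function(i) {
    social[runif(5) < 0.3]
  }))
  cls <- classify_ineads(make_profiles(sets))
  cls$admission_id <- adm$admission_id
  sm <- summarize_cohorts(adm, cls)
  expect_s3_class(sm, "ineads_cohort_summary")
  n_rows <- sm[sm$characteristic == "n", ]
  expect_equal(n_rows$n[n_rows$cohort == "full"], 60)
  expect_equal(n_rows$pct[n_rows$cohort == "full"], 100)
  # categorical counts add back to the cohort size
  gender_full <- sm[sm$cohort == "full" & sm$characteristic == "gender", ]
  expect_equal(sum(gender_full$n), 60)
  age_full <- sm[sm$cohort == "full" & sm$characteristic == "age", ]
  expect_equal(age_full$mean, round(mean(adm$age)))
})

test_that("summarize_cohorts requires a profile for every admission", {
  adm <- make_admissions(5)
  cls <- classify_ineads(make_profiles(list(character())))
  cls$admission_id <- adm$admission_id[1]
  expect_error(summarize_cohorts(adm, cls), "missing")
})

test_that("compare_cohorts matches direct Welch t and uncorrected chi-square", {
  adm <- make_admissions(80, seed = 7)
  social <- social_elevated_subcategories()
  sets <- withr::with_seed(8, lapply(1:80, function(i) social[runif(5) < 0.4]))
  cls <- classify_ineads(make_profiles(sets))
  cls$admission_id <- adm$admission_id
  cmp <- compare_cohorts(adm, cls, "possibility")
  sub <- adm[adm$admission_id %in% cohort_members(cls, "possibility"), ]

  tt <- t.test(adm$age, sub$age)
  expect_equal(cmp$statistic[cmp$characteristic == "age"],
               unname(tt$statistic))

  lev <- sort(unique(adm$gender))
  tab <- rbind(table(factor(adm$gender, lev)), table(factor(sub$gender, lev)))
  ct <- chisq.test(tab, correct = FALSE)
  expect_equal(cmp$statistic[cmp$characteristic == "gender"],
               unname(ct$statistic))
  expect_equal(cmp$sig_05, cmp$p_value < 0.05)
})

test_that("the uncorrected chi-square convention gives 38.1, not 36.2, on a 50/50 vs 90/10 split", {
  # Yates-corrected value would be 36.2; the package convention is the
  # uncorrected statistic, 2 * sum((o - e)^2 / e) = 38.095.
  tab <- rbind(c(50, 50), c(90, 10))
  expect_equal(unname(chisq.test(tab, correct = FALSE)$statistic),
               800 / 21, tolerance = 1e-10)
  expect_equal(round(800 / 21, 3), 38.095)
})

test_that("sample_gold_standard filters by qualifying codes, reproducibly", {
  notes <- tibble::tibble(
    note_id = sprintf("N%02d", 1:20),
    admission_id = rep(sprintf("A%02d", 1:10), each = 2)
  )
  diagnoses <- tibble::tibble(
    admission_id = sprintf("A%02d", 1:10),
    code = c("295.3", "F20.9", "4019", "042", "B20", "V700",
             "30000", "J18", "I10", "E11")
  )
  s1 <- sample_gold_standard(notes, diagnoses, 5, seed = 123)
  s2 <- sample_gold_standard(notes, diagnoses, 5, seed = 123)
  expect_identical(s1, s2)
  qualifying <- c("A01", "A02", "A04", "A05", "A07")
  expect_true(all(s1$admission_id %in% qualifying))
  expect_error(sample_gold_standard(notes, diagnoses, 100, seed = 1),
               "exceeds")
  no_qual <- dplyr::mutate(diagnoses, code = "E11")
  expect_error(sample_gold_standard(notes, no_qual, 2, seed = 1),
               "qualifying")
})
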