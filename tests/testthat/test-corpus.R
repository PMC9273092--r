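test_that("tokenize_text lowercases, drops stopwords, and records offsets", {
  tk <- tokenize_text("The patient Lives Alone at home.")
  expect_equal(tk$token, c("patient", "lives", "alone", "home"))
  # offsets point back into the original string
  expect_equal(substr("The patient Lives Alone at home.", tk$start[2], tk$end[2]),
               "Lives")
  expect_true(all(tk$sent_id == 1))
})

test_that("tokenize_text keeps intra-word hyphens and splits on slashes", {
  tk <- tokenize_text("code status dnr/dni, well-known to service")
  expect_true(all(c("dnr", "dni", "well-known") %in% tk$token))
})

test_that("de-identification spans become a single sentinel token", {
  tk <- tokenize_text("Seen by [**First Name (Titles) 123**] today")
  expect_true(deid_sentinel() %in% tk$token)
  expect_equal(sum(tk$token == deid_sentinel()), 1)
  # original bracket content never leaks through
  expect_false(any(grepl("titles|123", tk$token)))
})

test_that("sentence ids advance at terminators and newlines", {
  tk <- tokenize_text("no acute distress. lives alone\nplan unchanged")
  expect_equal(unique(tk$sent_id[tk$token %in% c("no", "acute", "distress")]), 1)
  expect_equal(unique(tk$sent_id[tk$token %in% c("lives", "alone")]), 2)
  expect_equal(unique(tk$sent_id[tk$token %in% c("plan", "unchanged")]), 3)
})

test_that("tokenize_text of empty or all-stopword text yields zero rows", {
  expect_equal(nrow(tokenize_text("")), 0)
  expect_equal(nrow(tokenize_text("the and of")), 0)
})

test_that("tokenize_notes stacks per-note tokens with note ids", {
  tk <- tokenize_notes(tiny_notes())
  expect_setequal(unique(tk$note_id), c("N1", "N2"))
  expect_true(all(c("lives", "alone") %in% tk$token[tk$note_id == "N1"]))
})

test_that("notes round-trip through write_notes / read_notes", {
  path <- withr::local_tempfile(fileext = ".csv")
  notes <- tiny_notes()
  write_notes(notes, path)
  back <- suppressMessages(read_notes(path))
  expect_equal(back, notes)
})

test_that("read_notes filters to included categories with a message", {
  path <- withr::local_tempfile(fileext = ".csv")
  notes <- tiny_notes()
  notes$category[2] <- "radiology"
  write_notes(notes, path)
  expect_message(back <- read_notes(path), "1 excluded")
  expect_equal(back$note_id, "N1")
})

test_that("read_notes warns and drops (or errors on) unknown categories", {
  path <- withr::local_tempfile(fileext = ".csv")
  notes <- tiny_notes()
  notes$category[2] <- "telepathy"
  write_notes(notes, path)
  expect_warning(
    back <- suppressMessages(read_notes(path)),
    "unknown category"
  )
  expect_equal(back$note_id, "N1")
  expect_error(
    suppressMessages(read_notes(path, unknown_category = "error")),
    "unknown category"
  )
})

test_that("read_notes rejects duplicate note ids and missing columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  notes <- tiny_notes()
  notes$note_id <- c("N1", "N1")
  write_notes(notes, path)
  expect_error(suppressMessages(read_notes(path)), "duplicate note_id")

  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(x = 1), path2)
  expect_error(read_notes(path2), "missing column")
})

test_that("admissions round-trip and are age-filtered on read", {
  path <- withr::local_tempfile(fileext = ".csv")
  adm <- tibble::tibble(
    admission_id = c("A1", "A2"), patient_id = c("P1", "P2"),
    age = c(70, 12), gender = c("female", "male"),
    ethnicity = c("white", "black"), admission_type = c("emergency", "elective"),
    insurance = c("medicare", "private"),
    expired_in_hospital = c(FALSE, FALSE), expired_in_followup = c(TRUE, FALSE)
  )
  write_admissions(adm, path)
  back <- suppressMessages(read_admissions(path))
  expect_equal(back$admission_id, "A1") # minor excluded by default min_age = 18
  expect_equal(back$age, 70)
  expect_true(back$expired_in_followup)
})

test_that("read_admissions validates ids, ages and mortality consistency", {
  write_adm <- function(adm) {
    path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
    write_admissions(adm, path)
    path
  }
  base <- tibble::tibble(
    admission_id = c("A1", "A2"), patient_id = c("P1", "P2"),
    age = c(70, 80), gender = "female", ethnicity = "white",
    admission_type = "emergency", insurance = "medicare",
    expired_in_hospital = FALSE, expired_in_followup = FALSE
  )
  dup <- base; dup$admission_id <- c("A1", "A1")
  expect_error(suppressMessages(read_admissions(write_adm(dup))),
               "duplicate admission_id")
  neg <- base; neg$age[1] <- -3
  expect_error(suppressMessages(read_admissions(write_adm(neg))),
               "negative age")
  # death in hospital implies death in follow-up
  bad <- base; bad$expired_in_hospital[1] <- TRUE
  expect_error(suppressMessages(read_admissions(write_adm(bad))),
               "expired")
})
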