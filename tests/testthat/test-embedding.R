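test_that("detect_phrases merges true collocations and leaves loose pairs", {
  # "living will" components only occur together; "plan review" co-occurs
  # sometimes, but both words are common in other company
  sents <- c(
    replicate(30, c("living", "will", "filed"), simplify = FALSE),
    replicate(10, c("plan", "review"), simplify = FALSE),
    purrr::map(1:45, ~ c("plan", paste0("x", .x))),
    purrr::map(1:45, ~ c(paste0("y", .x), "review"))
  )
  out <- detect_phrases(sents, min_count = 5)
  toks <- unlist(out)
  expect_true(any(startsWith(toks, "living_will")))
  expect_false("plan_review" %in% toks)
})

test_that("detect_phrases builds phrases beyond bigrams across passes", {
  sents <- replicate(30, c("do", "not", "resuscitate", "order"),
                     simplify = FALSE)
  out <- detect_phrases(sents, max_n = 3, min_count = 5)
  expect_true(any(grepl("do_not_resuscitate", unlist(out))))
})

test_that("npmi phrase scores are scale-free in [-1, 1]", {
  sents <- replicate(20, c("next", "of", "kin", "aware"), simplify = FALSE)
  sc <- ineads:::phrase_scores(sents, min_count = 5, scorer = "npmi")
  expect_true(all(sc$score >= -1 & sc$score <= 1))
  expect_true(sc$score[sc$left == "next" & sc$right == "of"] > 0.9)
})

test_that("embedding training is deterministic for a fixed seed", {
  sents <- withr::with_seed(3, replicate(
    200, sample(letters[1:12], 8, replace = TRUE), simplify = FALSE
  ))
  m1 <- train_embedding(sents, dim = 16, epochs = 2, seed = 5)
  m2 <- train_embedding(sents, dim = 16, epochs = 2, seed = 5)
  m3 <- train_embedding(sents, dim = 16, epochs = 2, seed = 6)
  expect_identical(m1$vectors, m2$vectors)
  expect_false(identical(m1$vectors, m3$vectors))
  expect_equal(rownames(m1$vectors), m1$vocab)
})

test_that("train_embedding rejects corpora below min_count", {
  expect_error(train_embedding(list(c("once"))), "vocabulary")
})

test_that("tokens sharing contexts embed closer than unrelated tokens", {
  # "alpha" and "beta" are interchangeable in their sentence frame;
  # "gamma" lives in a different frame.
  frame1 <- function(w) c("team", "spoke", w, "about", "plan", "today")
  frame2 <- function(w) c("drip", "titrated", w, "overnight", "rate", "stable")
  sents <- withr::with_seed(11, c(
    replicate(120, frame1(sample(c("alpha", "beta"), 1)), simplify = FALSE),
    replicate(120, frame2("gamma"), simplify = FALSE)
  ))
  m <- train_embedding(sents, dim = 32, epochs = 20)
  expect_gt(embedding_similarity(m, "alpha", "beta"),
            embedding_similarity(m, "alpha", "gamma"))
})

test_that("embeddings round-trip through save_embedding / load_embedding", {
  sents <- replicate(50, c("code", "status", "reviewed", "today"),
                     simplify = FALSE)
  m <- train_embedding(sents, dim = 8, epochs = 2)
  path <- withr::local_tempfile(fileext = ".txt")
  save_embedding(m, path)
  back <- load_embedding(path)
  expect_equal(back$vocab, m$vocab)
  expect_equal(back$vectors, m$vectors, tolerance = 1e-6)
})

test_that("suggest_synonyms excludes lexicon terms and honors rejections", {
  frame <- function(w) c("spoke", "with", w, "about", "plan", "today")
  sents <- withr::with_seed(12, replicate(
    200, frame(sample(c("husband", "spouse", "fiance"), 1)), simplify = FALSE
  ))
  m <- train_embedding(sents, dim = 16, epochs = 10)
  lx <- tibble::tibble(term = "husband", subcategory = "married",
                       provenance = "seed")
  sug <- suggest_synonyms(m, lx, "married", k = 5)
  expect_false("husband" %in% sug$candidate)
  expect_true(all(sug$decision == "pending"))
  expect_true(all(diff(sug$similarity) <= 0))
  sug2 <- suggest_synonyms(m, lx, "married", k = 5, rejected = sug$candidate[1])
  expect_false(sug$candidate[1] %in% sug2$candidate)
})

test_that("suggest_synonyms warns when no seed term is in the vocabulary", {
  sents <- replicate(30, c("unrelated", "tokens", "only", "here"),
                     simplify = FALSE)
  m <- train_embedding(sents, dim = 8, epochs = 2)
  lx <- tibble::tibble(term = "husband", subcategory = "married",
                       provenance = "seed")
  expect_warning(sug <- suggest_synonyms(m, lx, "married"), "vocabulary")
  expect_equal(nrow(sug), 0)
})

test_that("review_suggestions records decisions and tags provenance", {
  lx <- tibble::tibble(term = "husband", subcategory = "married",
                       provenance = "seed")
  sug <- tibble::tibble(query_term = "husband",
                        candidate = c("spouse", "fiance"),
                        similarity = c(0.9, 0.8), decision = "pending")
  res <- review_suggestions(lx, sug, tibble::tibble(
    candidate = c("spouse", "fiance"), decision = c("accept", "reject")
  ), "married")
  expect_true("spouse" %in% res$lexicon$term)
  expect_equal(res$lexicon$provenance[res$lexicon$term == "spouse"],
               "accepted_synonym")
  expect_false("fiance" %in% res$lexicon$term)
  expect_setequal(res$log$decision, c("accept", "reject"))

  expect_error(review_suggestions(lx, sug, tibble::tibble(
    candidate = "stranger", decision = "accept"
  ), "married"))
  expect_error(review_suggestions(lx, sug, tibble::tibble(
    candidate = "spouse", decision = "maybe"
  ), "married"))
})

test_that("expand_lexicon loops until no acceptance and never re-suggests rejects", {
  frame <- function(w) c("spoke", "with", w, "about", "plan", "today")
  sents <- withr::with_seed(13, replicate(
    300, frame(sample(c("husband", "spouse", "partner2", "fiance"), 1)),
    simplify = FALSE
  ))
  m <- train_embedding(sents, dim = 16, epochs = 10)
  lx <- tibble::tibble(term = "husband", subcategory = "married",
                       provenance = "seed")
  res <- expand_lexicon(m, lx, decide = decide_with_table("spouse"),
                        subcategories = "married", k = 5)
  expect_true("spouse" %in% res$lexicon$term)
  # every non-accepted candidate was rejected exactly once
  rejected <- res$log$candidate[res$log$decision == "reject"]
  expect_equal(anyDuplicated(rejected), 0)
})
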