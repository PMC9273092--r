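# Corpus language model (skip-gram with negative sampling) plus the
# collocation-merging and interactive synonym-expansion loop that grows the
# lexicon: the model proposes high-cosine neighbours of a subcategory's
# current terms; a reviewer accepts or rejects each; accepted terms join the
# lexicon with provenance "accepted_synonym"; the loop repeats until an
# iteration accepts nothing new.

#' Merge frequent collocations into phrase tokens
#'
#' Scores every adjacent token pair and merges pairs scoring at least
#' `threshold` into single underscore-joined items, greedily left to
#' right. The default scorer is normalized pointwise mutual information
#' (NPMI, in `[-1, 1]`), which is scale-free: the same threshold works for
#' small and large corpora. The alternative `"plain"` scorer is
#' `(count(ab) - min_count) * V / (count(a) * count(b))` (V = vocabulary
#' size), whose useful threshold grows with corpus size. The pass is
#' applied `max_n - 1` times so that up to `max_n`-gram phrases can form.
#'
#' @param sentences List of character vectors (token sequences, e.g. one per
#'   note from [tokenize_notes()]).
#' @param max_n Longest phrase length to form (>= 2).
#' @param min_count Minimum pair count for a merge candidate.
#' @param threshold Minimum collocation score for a merge (default 0.6, on
#'   the NPMI scale). Genuine lexicalized phrases, whose components rarely
#'   occur apart ("living will", "next of kin"), score near 1; word pairs
#'   that merely travel together because notes are formulaic score around
#'   0.3-0.5, so 0.6 keeps the former and rejects the latter.
#' @param scorer `"npmi"` (default) or `"plain"`.
#' @param delim Join character for merged phrases.
#' @return The sentence list with collocations merged.
#' @export
detect_phrases <- function(sentences, max_n = 3, min_count = 5,
                           threshold = 0.6, scorer = c("npmi", "plain"),
                           delim = "_") {
  stopifnot(max_n >= 2)
  scorer <- arg_match(scorer)
  for (pass in seq_len(max_n - 1)) {
    merges <- phrase_scores(sentences, min_count, scorer)
    merges <- merges[merges$score >= threshold, , drop = FALSE]
    if (nrow(merges) == 0) break
    pair_set <- paste(merges$left, merges$right, sep = "\r")
    sentences <- purrr::map(sentences, function(s) {
      n <- length(s)
      if (n < 2) return(s)
      is_pair <- paste(s[-n], s[-1], sep = "\r") %in% pair_set
      out <- character(n)
      k <- 0L
      i <- 1L
      while (i <= n) {
        if (i < n && is_pair[i]) {
          k <- k + 1L
          out[k] <- paste(s[i], s[i + 1L], sep = delim)
          i <- i + 2L
        } else {
          k <- k + 1L
          out[k] <- s[i]
          i <- i + 1L
        }
      }
      out[seq_len(k)]
    })
  }
  sentences
}

phrase_scores <- function(sentences, min_count, scorer = "npmi") {
  unigrams <- table(unlist(sentences, use.names = FALSE))
  pairs <- unlist(purrr::map(sentences, function(s) {
    n <- length(s)
    if (n < 2) return(character())
    paste(s[-n], s[-1], sep = "\r")
  }), use.names = FALSE)
  if (length(pairs) == 0) {
    return(tibble(left = character(), right = character(), score = double()))
  }
  pc <- table(pairs)
  pc <- pc[pc >= min_count]
  if (length(pc) == 0) {
    return(tibble(left = character(), right = character(), score = double()))
  }
  parts <- stringr::str_split_fixed(names(pc), "\r", 2)
  ca <- as.numeric(unigrams[parts[, 1]])
  cb <- as.numeric(unigrams[parts[, 2]])
  cab <- as.numeric(pc)
  if (scorer == "npmi") {
    N <- sum(unigrams)
    pa <- ca / N
    pb <- cb / N
    pab <- cab / N
    score <- log(pab / (pa * pb)) / (-log(pab))
  } else {
    V <- length(unigrams)
    score <- (cab - min_count) * V / (ca * cb)
  }
  tibble(left = parts[, 1], right = parts[, 2], score = score)
}

#' Train a skip-gram word-embedding model
#'
#' Skip-gram with negative sampling over the (phrase-merged) token corpus,
#' single-threaded with its own seeded generator so that identical inputs
#' and seed give bit-identical vectors.
#'
#' @param sentences List of character vectors (after [detect_phrases()] if
#'   phrase vocabulary items are wanted).
#' @param dim Vector dimensionality (default 100).
#' @param window Maximum context window (default 5; shrunk dynamically per
#'   position as in classic word2vec).
#' @param min_count Tokens rarer than this are dropped from the vocabulary
#'   (default 5).
#' @param epochs Training passes (default 10).
#' @param negative Negative samples per positive pair (default 5).
#' @param alpha Initial learning rate (default 0.025, decayed linearly).
#' @param seed Integer seed for initialization and sampling.
#' @return An object of class `ineads_embedding`: list with `vocab`
#'   (character), `counts`, `vectors` (vocab x dim matrix, rownames =
#'   vocab), `dim`, and `params`.
#' @export
train_embedding <- function(sentences, dim = 100, window = 5, min_count = 5,
                            epochs = 10, negative = 5, alpha = 0.025,
                            seed = 1) {
  counts <- table(unlist(sentences, use.names = FALSE))
  counts <- counts[counts >= min_count]
  if (length(counts) == 0) {
    abort("empty vocabulary: no token reaches min_count")
  }
  vocab <- names(counts)
  ids <- seq_along(vocab) - 1L
  names(ids) <- vocab
  corpus <- purrr::map(sentences, function(s) {
    v <- unname(ids[s])
    v[is.na(v)] <- -1L
    as.integer(v)
  })
  corpus <- corpus[lengths(corpus) > 0]
  if (length(corpus) == 0) abort("empty corpus after vocabulary filtering")
  vec <- .sgns_train(corpus, as.integer(counts), as.integer(dim),
                     as.integer(window), as.integer(negative),
                     as.integer(epochs), alpha, as.integer(seed))
  rownames(vec) <- vocab
  structure(
    list(
      vocab = vocab, counts = as.integer(counts), vectors = vec,
      dim = as.integer(dim),
      params = list(window = window, min_count = min_count, epochs = epochs,
                    negative = negative, alpha = alpha, seed = seed)
    ),
    class = "ineads_embedding"
  )
}

#' @export
print.ineads_embedding <- function(x, ...) {
  cat("<ineads embedding> ", length(x$vocab), " vocabulary items, dim ",
      x$dim, " (seed ", x$params$seed, ")\n", sep = "")
  invisible(x)
}

#' Save / load an embedding model as plain text
#'
#' The format is a header line `dim window min_count epochs negative alpha
#' seed` followed by one `token v1 ... v_dim` line per vocabulary item.
#'
#' @param model An `ineads_embedding`.
#' @param path File path.
#' @return `save_embedding` the model invisibly; `load_embedding` a model.
#' @export
save_embedding <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  p <- model$params
  writeLines(paste(model$dim, p$window, p$min_count, p$epochs, p$negative,
                   p$alpha, p$seed), con)
  body <- paste(model$vocab, model$counts,
                apply(model$vectors, 1, paste, collapse = " "))
  writeLines(body, con)
  invisible(model)
}

#' @rdname save_embedding
#' @export
load_embedding <- function(path) {
  lines <- readLines(path)
  hdr <- as.numeric(strsplit(lines[1], " ", fixed = TRUE)[[1]])
  body <- strsplit(lines[-1], " ", fixed = TRUE)
  vocab <- vapply(body, `[`, character(1), 1)
  counts <- as.integer(vapply(body, `[`, character(1), 2))
  vec <- t(vapply(body, function(x) as.numeric(x[-(1:2)]), numeric(hdr[1])))
  rownames(vec) <- vocab
  structure(
    list(vocab = vocab, counts = counts, vectors = vec, dim = as.integer(hdr[1]),
         params = list(window = hdr[2], min_count = hdr[3], epochs = hdr[4],
                       negative = hdr[5], alpha = hdr[6], seed = hdr[7])),
    class = "ineads_embedding"
  )
}

#' Cosine similarity between two vocabulary items
#'
#' @param model An `ineads_embedding`.
#' @param a,b Vocabulary items (phrases underscore-joined).
#' @return Cosine similarity in `[-1, 1]`; `NA` if either item is out of
#'   vocabulary.
#' @export
embedding_similarity <- function(model, a, b) {
  if (!(a %in% model$vocab) || !(b %in% model$vocab)) return(NA_real_)
  va <- model$vectors[a, ]
  vb <- model$vectors[b, ]
  sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
}

unit_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

# vocab form of a normalized (space-joined) lexicon term
vocab_form <- function(term, delim = "_") gsub(" ", delim, term, fixed = TRUE)
display_form <- function(item, delim = "_") gsub(delim, " ", item, fixed = TRUE)

#' Suggest synonym candidates for a subcategory
#'
#' Pools the nearest neighbours of each of the subcategory's current terms
#' and ranks pooled candidates by their maximum cosine similarity to any
#' seed term (rather than to a centroid: subcategories are semantically
#' heterogeneous). Candidates already in the lexicon (any subcategory) or
#' previously rejected are excluded. Ties are broken lexicographically.
#'
#' @param model An `ineads_embedding`.
#' @param lexicon A lexicon tibble.
#' @param subcategory Subcategory name to expand.
#' @param k Maximum number of suggestions (>= 1).
#' @param rejected Character vector of previously rejected candidate terms
#'   (space-joined form), never re-suggested.
#' @return A tibble of class columns `query_term`, `candidate`,
#'   `similarity`, `decision` (all `"pending"`), at most `k` rows, sorted by
#'   similarity descending. Empty (with a warning) when no subcategory term
#'   is in the model vocabulary.
#' @export
suggest_synonyms <- function(model, lexicon, subcategory, k = 10,
                             rejected = character()) {
  stopifnot(k >= 1)
  lx <- as_tibble(lexicon)
  seeds <- unique(lx$term[lx$subcategory == subcategory])
  seed_items <- vocab_form(seeds)
  in_vocab <- seed_items %in% model$vocab
  if (!any(in_vocab)) {
    warn(paste0("no term of subcategory '", subcategory,
                "' is in the model vocabulary"))
    return(tibble(query_term = character(), candidate = character(),
                  similarity = double(), decision = character()))
  }
  seed_items <- seed_items[in_vocab]
  seeds <- seeds[in_vocab]

  U <- unit_rows(model$vectors)
  sims <- U %*% t(U[seed_items, , drop = FALSE]) # |V| x n_seeds
  best <- apply(sims, 1, max)
  best_seed <- seeds[apply(sims, 1, which.max)]

  exclude_items <- unique(c(vocab_form(lx$term), vocab_form(rejected),
                            seed_items))
  cand <- tibble(
    item = rownames(U), similarity = as.numeric(best), query_term = best_seed
  ) %>%
    filter(!(.data$item %in% exclude_items)) %>%
    mutate(candidate = display_form(.data$item)) %>%
    filter(!(.data$candidate %in% lx$term)) %>%
    arrange(dplyr::desc(.data$similarity), .data$candidate) %>%
    slice_head(n = k)
  tibble(query_term = cand$query_term, candidate = cand$candidate,
         similarity = cand$similarity, decision = "pending")
}

#' Apply accept/reject decisions to synonym suggestions
#'
#' Accepted candidates join the lexicon under the given subcategory with
#' `provenance = "accepted_synonym"`; every decision is appended to the
#' decision log so rejected candidates are never re-suggested.
#'
#' @param lexicon A lexicon tibble.
#' @param suggestions Suggestion tibble from [suggest_synonyms()].
#' @param decisions Tibble with columns `candidate` and `decision`
#'   (`"accept"` or `"reject"`); every row must reference a pending
#'   suggestion.
#' @param subcategory Subcategory the suggestions were generated for.
#' @param log Existing decision-log tibble to append to (or `NULL`).
#' @return A list with elements `lexicon` (updated), `log` (tibble with
#'   `subcategory`, `query`, `candidate`, `similarity`, `decision`,
#'   `timestamp`), and `n_accepted`.
#' @export
review_suggestions <- function(lexicon, suggestions, decisions, subcategory,
                               log = NULL) {
  unknown <- setdiff(decisions$candidate, suggestions$candidate)
  if (length(unknown) > 0) {
    abort(paste0("decision(s) for unknown candidate(s): ",
                 paste(unknown, collapse = ", ")))
  }
  bad <- setdiff(unique(decisions$decision), c("accept", "reject"))
  if (length(bad) > 0) {
    abort(paste0("invalid decision value(s): ", paste(bad, collapse = ", ")))
  }
  dec <- suggestions %>%
    inner_join(decisions, by = "candidate", suffix = c("", ".d")) %>%
    mutate(decision = .data$decision.d) %>%
    select("query_term", "candidate", "similarity", "decision")

  accepted <- dec$candidate[dec$decision == "accept"]
  lx <- as_tibble(lexicon)
  if (length(accepted) > 0) {
    schema <- subcategory_schema()
    row <- schema[schema$subcategory == subcategory, ]
    add <- tibble(
      term = accepted, subcategory = subcategory, domain = row$domain,
      potential = row$potential, provenance = "accepted_synonym"
    )
    add <- anti_join(add, lx, by = c("term", "subcategory"))
    lx <- bind_rows(lx, add)
  }
  entry <- tibble(
    subcategory = subcategory, query = dec$query_term,
    candidate = dec$candidate, similarity = dec$similarity,
    decision = dec$decision,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  list(
    lexicon = new_lexicon(lx, version = attr(lexicon, "version")),
    log = bind_rows(log, entry),
    n_accepted = length(accepted)
  )
}

#' Iterative lexicon expansion loop
#'
#' For each subcategory in turn, queries the model for synonym suggestions,
#' obtains accept/reject decisions from `decide`, and updates the lexicon;
#' the loop repeats until a full iteration accepts zero new terms (or
#' `max_iter` is reached). Rejected candidates are never re-suggested, so
#' the loop terminates: the lexicon grows monotonically and the candidate
#' pool is finite.
#'
#' @param model An `ineads_embedding`.
#' @param lexicon Starting lexicon.
#' @param decide Decision callback: `function(suggestions, subcategory)`
#'   returning a decisions tibble (`candidate`, `decision`). See
#'   [decide_with_table()] for a batch-mode callback and
#'   [decide_interactively()] for a console prompt.
#' @param subcategories Subcategories to expand (default: all 17).
#' @param k Suggestions per subcategory per iteration.
#' @param max_iter Safety cap on iterations.
#' @return A list with `lexicon`, `log`, and `iterations`.
#' @export
expand_lexicon <- function(model, lexicon, decide,
                           subcategories = subcategory_schema()$subcategory,
                           k = 10, max_iter = 10) {
  log <- NULL
  iter <- 0L
  repeat {
    iter <- iter + 1L
    accepted_this_iter <- 0L
    for (sub in subcategories) {
      rejected <- if (is.null(log)) character() else {
        log$candidate[log$decision == "reject" & log$subcategory == sub]
      }
      sugg <- withCallingHandlers(
        suggest_synonyms(model, lexicon, sub, k = k, rejected = rejected),
        warning = function(w) invokeRestart("muffleWarning")
      )
      if (nrow(sugg) == 0) next
      dec <- decide(sugg, sub)
      if (is.null(dec) || nrow(dec) == 0) next
      res <- review_suggestions(lexicon, sugg, dec, sub, log = log)
      lexicon <- res$lexicon
      log <- res$log
      accepted_this_iter <- accepted_this_iter + res$n_accepted
    }
    if (accepted_this_iter == 0 || iter >= max_iter) break
  }
  list(lexicon = lexicon, log = log, iterations = iter)
}

#' Batch decision callback from a reference table
#'
#' Accepts exactly the candidates present in `accept_terms`; rejects all
#' others. Useful for scripted expansion runs and tests.
#'
#' @param accept_terms Character vector of candidate terms to accept
#'   (space-joined form).
#' @return A callback for [expand_lexicon()].
#' @export
decide_with_table <- function(accept_terms) {
  force(accept_terms)
  function(suggestions, subcategory) {
    tibble(
      candidate = suggestions$candidate,
      decision = if_else(suggestions$candidate %in% accept_terms,
                         "accept", "reject")
    )
  }
}

#' Console decision callback
#'
#' Prompts y/n for each suggestion on the console; intended for interactive
#' vocabulary-explorer sessions, not for scripts.
#'
#' @return A callback for [expand_lexicon()].
#' @export
decide_interactively <- function() {
  function(suggestions, subcategory) {
    ans <- vapply(seq_len(nrow(suggestions)), function(i) {
      prompt <- sprintf("[%s] accept '%s' (sim %.3f vs '%s')? [y/N] ",
                        subcategory, suggestions$candidate[i],
                        suggestions$similarity[i], suggestions$query_term[i])
      r <- readline(prompt)
      if (tolower(substr(r, 1, 1)) == "y") "accept" else "reject"
    }, character(1))
    tibble(candidate = suggestions$candidate, decision = ans)
  }
}

#' Write a decision log as TSV
#'
#' @param log Decision-log tibble from [expand_lexicon()].
#' @param path Output path.
#' @return The log, invisibly.
#' @export
write_decision_log <- function(log, path) {
  readr::write_tsv(log, path)
  invisible(log)
}
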