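# Shared test helpers: independent re-statements of package semantics used
# as oracles in property tests.

# Brute-force mention finder: tests every token window against every
# lexicon term, then resolves overlaps longest-match-first, then leftmost
# (ties by subcategory, then term), with global token consumption.
oracle_mentions <- function(tokens, lexicon) {
  toks <- tokens$token
  nt <- length(toks)
  cand <- list()
  for (r in seq_len(nrow(lexicon))) {
    tt <- strsplit(lexicon$term[r], " ", fixed = TRUE)[[1]]
    L <- length(tt)
    if (L > nt) next
    for (s in seq_len(nt - L + 1)) {
      if (all(toks[s:(s + L - 1)] == tt)) {
        cand[[length(cand) + 1]] <- data.frame(
          subcategory = lexicon$subcategory[r], term = lexicon$term[r],
          token_start = s, token_end = s + L - 1, len = L,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(cand) == 0) {
    return(data.frame(subcategory = character(), term = character(),
                      token_start = integer(), token_end = integer(),
                      stringsAsFactors = FALSE))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$len, cand$token_start, cand$subcategory, cand$term), ]
  consumed <- logical(nt)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    span <- cand$token_start[i]:cand$token_end[i]
    if (!any(consumed[span])) {
      keep[i] <- TRUE
      consumed[span] <- TRUE
    }
  }
  out <- cand[keep, c("subcategory", "term", "token_start", "token_end")]
  out <- out[order(out$token_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random telegraphic note built from lexicon-term tokens plus filler, so
# overlap resolution is actually exercised.
random_note_text <- function(lexicon, max_tokens = 30) {
  filler <- c("stable", "overnight", "monitor", "labs", "pending", "plan",
              "continue", "tolerating", "afebrile", "review")
  pieces <- character()
  n <- 0
  while (n < max_tokens) {
    if (runif(1) < 0.4) {
      piece <- sample(lexicon$term, 1)
    } else {
      piece <- sample(filler, 1)
    }
    n <- n + length(strsplit(piece, " ", fixed = TRUE)[[1]])
    if (n > max_tokens) break
    pieces <- c(pieces, piece)
  }
  paste(pieces, collapse = " ")
}

# Minimal two-note corpus used across unit tests.
tiny_notes <- function() {
  tibble::tibble(
    note_id = c("N1", "N2"),
    patient_id = c("P1", "P1"),
    admission_id = c("A1", "A1"),
    category = c("nursing", "physician"),
    chart_time = c("2010-01-01 08:00:00", "2010-01-02 08:00:00"),
    text = c(
      "Pt is a 73 yo F, lives alone, divorced. Vital signs stable.",
      "Social work note: no contact from family despite attempts."
    )
  )
}
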