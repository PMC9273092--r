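---
title: "Methods: detecting patients without evident advance directives or surrogates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting patients without evident advance directives or surrogates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ineads)
```

## The problem

When a critically ill patient loses decision-making capacity, clinicians
turn to an advance directive or a surrogate decision maker. A patient who
is *Incapacitated with No Evident Advance Directives or Surrogates*
(INEADS) has neither, and decisions about their care are made without
direct knowledge of their preferences. Identifying these patients early —
ideally before capacity is lost — would let care teams start advance-care
planning while it can still involve the patient.

The social context that predicts this state (marital status, who the
patient lives with, caregiver and community support, documented proxies,
code-status paperwork) is rarely coded in structured fields. It lives in
free-text clinical notes, in telegraphic fragments such as "pt lives alone,
never married" or "no contact from family despite multiple attempts". This
package implements a lexicon-based natural-language-processing pipeline
that extracts these fragments and aggregates them into admission-level
INEADS cohort labels, together with the evaluation protocol for scoring
the extraction against gold-standard chart review, and a synthetic corpus
generator so that every stage is testable without access to protected
health data.

## Conceptual model

Seventeen **subcategories** of documentation are organized in three
domains:

```{r}
subcategory_schema()
```

Each subcategory carries a *potential*: documentation of a spouse or an
involved caregiver makes INEADS status less likely (**reduced** potential),
while documentation of living alone or being unable to reach family makes
it more likely (**elevated**). Five elevated subcategories describing
social circumstances — unmarried, living alone, transitionally situated
(housing instability), surrogate unidentified, and advance directives
unavailable — drive the cohort rules:

* **possibility cohort** — the admission documents at least one of the
  five;
* **high-likelihood cohort** — at least four of the five, further split by
  whether any reduced-potential subcategory is also documented (a spouse
  mentioned alongside four elevated markers is a different situation from
  four elevated markers alone).

The thresholds are arguments of `classify_ineads()`, defaulting to 1
and 4.

## Pipeline stages and design choices

### Tokenization

`tokenize_text()` lowercases, splits on anything that is not a letter,
digit or intra-word hyphen, removes a deliberately small stopword list,
and records character offsets and sentence ids (sentences end at
`. ! ? ;` and newlines, which in telegraphic nursing notes act as
terminators). Two choices matter:

* The stopword list excludes `no`, `not`, `never`, `will`, `with`,
  `from`, `his`, `her`. Generic NLP stopword lists contain these words,
  but here they are load-bearing: "no living will" loses its meaning
  without "no" and "will".
* De-identification placeholders (`[** ... **]`) are collapsed to a
  single sentinel token, `xxphixx`, so they can never match a lexicon
  term yet still occupy a token position for negation scoping.

The lexicon is normalized with the *same* tokenizer and stopword list at
construction time, so matching is exact sequence equality over tokens —
there is no way for the two sides to disagree about normalization.

### Matching and overlap resolution

`find_mentions()` enumerates every position where a lexicon term's token
sequence occurs, then resolves overlaps **longest-match-first, then
leftmost**, with accepted mentions consuming their tokens. This gives the
intuitive reading of "pt never married": the two-token term "never
married" (unmarried) wins over the embedded one-token term "married"
(married), and the consumed token cannot be re-used. A brute-force window
enumerator re-implementing this rule is kept in the test suite as an
oracle, and the matcher is property-tested against it on random notes.

### Negation

`detect_negation()` implements a trigger/scope model: a forward trigger
("no", "denies", "without", ...) negates a mention starting within six
tokens after it; a backward trigger ("unlikely", "unconfirmed", ...)
negates within six tokens before it. Scope is broken by sentence
boundaries and by "but". One exemption is essential: terms that
*lexically begin with* a trigger token ("no living will", "no contact
from family", "never married") are never flagged — the negation is part of
the concept, not a denial of it. Without the exemption, the subcategories
that indicate *absence* of support would be systematically suppressed.

Negated mentions are retained in the annotation table (flagged
`negated = TRUE`) but excluded from note-level subcategory assignment and
from everything downstream.

### Embedding-driven lexicon expansion

A seed lexicon cannot anticipate every way a ward writes "husband". The
expansion loop addresses this:

1. `detect_phrases()` merges collocations into single tokens so that
   multi-word vocabulary ("living will", "next of kin") gets a vector.
   The scorer is **normalized pointwise mutual information** (NPMI), with
   a merge threshold of 0.6. NPMI was chosen over the classic
   `count`-ratio scorer because it is scale-free: the same threshold
   works for a few hundred notes and for hundreds of thousands, whereas
   the ratio scorer's useful threshold grows with vocabulary size. The
   threshold sits between two empirically well-separated regimes:
   genuine lexicalized phrases, whose components rarely occur apart,
   score near 1.0, while word pairs that merely travel together because
   notes are formulaic score around 0.3–0.5.
2. `train_embedding()` trains skip-gram with negative sampling (window 5,
   dimension 100, 10 epochs, 5 negative samples, unigram^0.75 sampling
   table, linearly decaying learning rate). The trainer is implemented in
   C++ with its own seeded generator, single-threaded, so identical input
   and seed give bit-identical vectors — reviewability of an interactive
   expansion session depends on being able to reproduce it.
3. `suggest_synonyms()` pools nearest neighbours of a subcategory's
   current terms and ranks candidates by their maximum cosine similarity
   to any seed term (not to a centroid — subcategories are semantically
   heterogeneous: "chaplain" and "attends church" are both
   religious-connection terms but not neighbours of each other).
4. `expand_lexicon()` drives the accept/reject loop: accepted candidates
   join the lexicon with `provenance = "accepted_synonym"`, rejected
   candidates are logged and never re-suggested, and the loop stops when
   a full iteration accepts nothing. Decisions come from a callback —
   `decide_interactively()` for console review, `decide_with_table()` for
   scripted runs.

### Evaluation conventions

`evaluate_annotations()` scores note-level subcategory assignment against
chart review: per-subcategory precision (positive predictive value),
recall (sensitivity), and F, with the **overall row as the unweighted
macro mean over subcategories that have observations** — rare
subcategories count as much as common ones, which is the appropriate
summary when the rare ones (hospice, transitionally situated) are the
clinically decisive ones. Subcategories never predicted have undefined
precision and are reported as `NA`, not zero. Documentation frequencies
(`frequency_table()`) are percentages of the notes carrying at least one
label. `cohens_kappa()` reports observed and expected agreement as
attributes and handles the degenerate `p_e = 1` case explicitly.

The package ships a published reference validation table
(`reference_metrics()`, `reference_counts()`) and regression-tests its own
arithmetic — F from precision/recall, macro averaging, percentage
computation — against those printed values.

### Cohort statistics

`summarize_cohorts()` produces the table-one style summary (n (%), mean
(SD) age, mortality) for the full, possibility and high-likelihood
cohorts. `compare_cohorts()` runs Welch's t-test for age and chi-square
tests *without* continuity correction for categorical characteristics,
comparing each subcohort against the **full** cohort that contains it.
That overlap makes the tests anti-conservative; it is retained
deliberately because it matches the source protocol this package
replicates, and it is flagged in the function documentation as a caveat
rather than silently corrected.

## The synthetic corpus generator

`generate_corpus()` produces notes, admissions, and an exact plant ledger:
per admission, subcategories are planted independently with configured
probabilities, each plant renders a hand-written telegraphic template with
a term from the seed vocabulary, optionally wrapped in a negation phrase
or substituted by a held-out synonym, and padded with distractor
sentences. Demographics and mortality are sampled per admission, with
mortality logit-enriched by the number of social-elevated subcategories
planted, so that cohort comparisons have signal to find.

Two generator design points are worth spelling out:

* **Template scaffolds avoid the lexicon** (checked by a test that
  annotates every scaffold and expects zero mentions), so in a noiseless
  configuration precision and recall are exactly 1.0 by construction —
  any deviation is a pipeline bug, not generator noise.
* **The words adjacent to the term slot are shared across all seventeen
  subcategories**, while the rest of each template uses
  subcategory-topical vocabulary. Real notes reuse framing words
  ("currently", "documented", "per") across many contexts; a generator
  that repeated whole sentences verbatim would make every scaffold-term
  pair a perfect collocation, and phrase detection would rightly fuse the
  planted terms into their scaffolds. The shared framing keeps planted
  terms as their own tokens, and the topical remainder gives the
  embedding the discriminative context it needs to rank a subcategory's
  held-out synonym above other subcategories' terms.

Limitations of the generator are equally deliberate: it does not model
clinical language beyond the template level, does not generate diagnosis
code profiles, and its notes are far shorter than real ones. It exists to
give every pipeline stage a corpus with known ground truth, not to be
mistaken for clinical text.

One lexicon subtlety inherited from the domain: "code status DNR/DNI" is
treated as *advance directives available* — a documented code status is a
recorded preference — even though a DNR order is not a full advance
directive. Users who disagree can move the term in a custom lexicon file.

## Problem sizes and runtime

The default study conditions used throughout the tests: 1,000 admissions
(~3,000 notes) for noiseless recovery, which annotates in a few seconds;
2,000 admissions with a 50% synonym-substitution rate for embedding
training and synonym recovery, which runs end to end in well under a
minute; all 131,072 subcategory subsets for cohort-rule fidelity, which
takes a few seconds. Everything is single-threaded and deterministic
given a seed.

## Worked example

```{r, eval = FALSE}
sim <- generate_corpus(synthetic_config(n_admissions = 200))
pl <- run_pipeline(sim$notes, sim$admissions)
pl
tidy(evaluate_annotations(pl$annotations, sim$gold_notes,
                          note_ids = sim$notes$note_id))
```
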