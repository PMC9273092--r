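Package: ineads
Title: Lexicon-Based Detection of Patients Lacking Advance Directives and
    Surrogates in Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A natural-language-processing pipeline for flagging acute-care
    admissions whose patients may be Incapacitated with No Evident Advance
    Directives or Surrogates (INEADS). Free-text clinical notes are scanned
    with a 17-subcategory lexicon covering surrogate decision makers,
    advance directives and decisional capacity; mentions are negation-aware;
    a skip-gram word-embedding model supports interactive synonym expansion
    of the lexicon; note-level annotations are aggregated to admissions and
    classified into "possibility" and "high likelihood" INEADS cohorts; and
    an evaluation module scores annotations against gold-standard chart
    review (per-subcategory precision, recall, F, macro averages, Cohen's
    kappa). A synthetic corpus generator with known ground truth makes every
    stage testable without access to protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    Rcpp,
    withr
LinkingTo:
    Rcpp
Suggests:
    e1071,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
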