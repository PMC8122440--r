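Package: clinspell
Title: Real-Word Spelling Error Synthesis and Correction Scoring for Clinical Spanish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building parallel corpora of real-word spelling errors
    in Spanish clinical text and for scoring automatic correctors. Provides
    rule-based generators for six error types (grammatical genre, number,
    genre-number, homophones, suggestion-based and subject-verb concordance)
    constrained by a corpus-derived lexicon, text preprocessing (sentence
    splitting, number masking, punctuation separation, length filtering), two
    parallel-dataset compilation strategies, an insert/delete-only edit
    distance post-processor for corrector output, per-error-type
    recall/precision/F0.5 evaluation, and a self-contained synthetic
    clinical-Spanish corpus generator with reference correctors.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
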