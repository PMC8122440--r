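# clinspell

Real-word spelling errors — misspellings whose result is itself a valid
word (*unida* for *unido*, *ha* for *a*) — are invisible to dictionary
lookup and especially harmful in clinical text, where an automatic tool
that silently "corrects" a note can degrade patient records. Training and
benchmarking correctors for Spanish clinical text requires parallel
erroneous/correct corpora that do not exist naturally, so they must be
synthesized.

`clinspell` builds those corpora and scores correctors against them. It
provides, as composable R functions plus a thin command-line front end:

* **Preprocessing** — sentence splitting, digit-run masking with a constant
  token, replacement of non-alphanumeric symbols by blanks with sentence
  punctuation kept as standalone tokens, case preserved, and token-count
  filtering (keep length in `(5, 40]`, optional for small corpora).
* **Lexicon** — a corpus-derived word/frequency dictionary that defines
  real-word membership, ranks spelling suggestions by
  (edit distance, frequency, lexicography), and identifies regular verb
  forms through packaged conjugation tables (`-ar`/`-er`/`-ir`, present /
  imperfect past / future, indicative and subjunctive, plus the full
  paradigm of *haber*).
* **Error generation** — six rule groups that turn one correct word into a
  real-word error: grammatical **genre** (suffix swaps such as
  `-ido`/`-ida` over the eleven common suffix bases), **number**
  (vowel `+s`, consonant `+es`, and inverses), **genre-number** (their
  composition), **homophones** (`b`/`v`, `ll`/`y`, silent `h` insertion and
  deletion), **suggestion-based** (first ranked lexicon suggestion not
  producible by the other groups), and **subject-verb concordance** (random
  person swap within the same tense and mood). Every candidate must be
  attested in the lexicon and lie within 3 insert/delete edit operations of
  the original (6 for concordance).
* **Dataset compilation** — strategy 1 (up to one erroneous sentence per
  error type per correct sentence, plus the correct sentence) and
  strategy 2 (exactly one output per sentence, groups tried in random
  order), train/validation/test splitting with a type-balanced test set,
  and line-parallel source/target files with JSON-lines metadata.
* **Correction post-processing** — insert/delete-only Levenshtein distance
  (`|a| + |b| − 2·LCS(a,b)`, computed in C++), `<unknown>`-token fallback to
  the source word, and threshold gating of predicted tokens (default 6).
* **Evaluation** — per-error-type and overall recall, precision and
  F0.5 = 1.25·P·R / (0.25·P + R), the standard correction score in which
  precision outweighs recall.
* **Synthetic data** — a self-contained generator of clinical-register
  Spanish sentences whose vocabulary is closed under all rule paradigms, so
  the whole pipeline runs with no external corpus, plus oracle, identity
  and context-bigram frequency reference correctors.

## Worked example

Generate a synthetic corpus, plant one error per sentence, correct the test
split with the bigram-vote baseline, gate its output, and score it:

```r
library(clinspell)

tables <- load_conjugations()
corpus <- generate_corpus(3000, seed = 42, tables = tables)
lex    <- synthetic_lexicon(corpus, tables)

ds <- compile_strategy2(corpus, lex, tables, seed = 8)
ds <- split_dataset(ds, n_validation = 300, n_test = 600, seed = 3)
test  <- ds[ds$split == "test", ]
train <- sentence_tokens(ds$source[ds$split == "train"])

pred <- frequency_corrector(test, train, lex, tables)
src  <- sentence_tokens(test$source)
prd  <- sentence_tokens(pred)
post <- vapply(seq_len(nrow(test)), function(i)
  paste(resolve_prediction(src[[i]], prd[[i]], threshold = 6),
        collapse = " "), character(1))

evaluate_corrections(test, post)
```

```
   error_type total_errors corrected bad_corrections recall precision   f05
        genre          100        53              95  53.00     35.81 38.29
       number          100        82              81  82.00     50.31 54.52
 genre_number          100        51              75  51.00     40.48 42.22
    homophone          100        93              64  93.00     59.24 63.87
   suggestion          100         0              82   0.00      0.00  0.00
  concordance          100        32              87  32.00     26.89 27.78
      overall          600       311             484  51.83     39.12 41.14
(0/0 ratios reported as 0)
```

The test split is balanced at 100 errors per type. The baseline restores a
token only when an alternative wins the summed left+right bigram vote, so
it recovers morphological and homophone errors whose correction dominates
in context (93% of homophone errors here), cannot restore suggestion-based
errors (their corrections are outside its rule-derived candidate sets —
recall 0), and pays for its greed in precision: 484 well-formed tokens were
"corrected" into context-frequent alternatives. F0.5 weights that precision
loss heavily, which is exactly why it is the reported score.

A shell version of the same pipeline is available through
`exec/clinspell` (`simulate`, `compile`, `correct-postprocess`,
`evaluate`; see `--help` of each subcommand).

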