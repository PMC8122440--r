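---
title: "Synthesizing and scoring real-word errors in clinical Spanish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthesizing and scoring real-word errors in clinical Spanish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinspell)
```

## The problem and the model

A real-word error is a misspelling whose outcome is itself a valid word:
*unida* for *unido*, *ha* for *a*, *llevas* for *llevan*. No dictionary
lookup can flag it; only sentence context can. Correctors for this problem
— whether sequence-to-sequence models or n-gram baselines — need parallel
corpora of (erroneous, correct) sentence pairs, and for Spanish clinical
text such corpora must be synthesized from clean text.

`clinspell` implements that synthesis as a deterministic, auditable rule
pipeline. The underlying model of an error is purely orthographic: a
single-token substitution, produced by a small string rewrite, whose result
is attested in a corpus-derived lexicon (the *real-word gate*) and lies
within a bounded insert/delete edit distance of the original. No
part-of-speech tagging or parsing is assumed anywhere: rules fire on
surface strings and the lexicon alone separates words from non-words. That
assumption is what makes the method applicable to raw clinical text, and it
is also its main limitation — the rules occasionally produce a
grammatically coherent sentence (*casas* for *casos* next to an invariant
modifier), which is precisely the ambiguity real correctors must face.

## Preprocessing

Raw text is split into sentences by a rule-based splitter (a terminator
`.?!` followed by whitespace and an upper-case letter or digit starts a new
sentence); sentence-leading semicolons, an artefact of clause-joined
clinical prose, are stripped. Each sentence is then normalized:

1. every maximal digit run is replaced by a constant mask token (default
   `"NUM"`); decimal and slash-separated figures (`36,5`, `120/80`) mask
   each run independently, so the separator survives as punctuation or is
   dropped with the other symbols;
2. every character that is not a letter, digit or retained punctuation is
   replaced by a blank;
3. retained punctuation — the whitelist `. , ; : ? !` — is separated into
   standalone tokens.

The whitelist resolves a genuine tension between "non-alphanumeric symbols
become blanks" and "punctuation is kept as separate tokens": we keep
exactly the sentence-level punctuation a clinical note uses and discard
parentheses, slashes, quotes, percent signs and ordinal markers. Letter
case is never modified, because a lower-cased sentence start is itself a
real-word error a corrector should see. Normalization is idempotent, which
the tests exercise.

The length filter keeps sentences with more than 5 and at most 40 tokens
(very short fragments are mostly markup residue and link titles; very long
sentences are hard for sequence models). For small domain corpora the
filter can be disabled, and the synthetic generator emits sentences inside
the admissible band by construction.

## Lexicon and conjugation tables

The lexicon maps word forms to occurrence counts. Membership is exact and
case-sensitive; the default count floor is 1 (every attested form is a real
word — frequency floors are an embedding-training concern, not a
dictionary one) and configurable. Suggestions for a word are all entries
within a configurable insert/delete distance (default 3), ranked by
distance, then frequency (descending), then byte-wise lexicographic order
— a deterministic total order.

Verb identification uses packaged YAML tables of regular person
terminations for the three conjugation classes, across present, past and
future tense in indicative and subjunctive mood, plus the complete paradigm
of the auxiliary *haber*. Two table decisions deserve a note:

* Spanish has two simple pasts. The tables use the **imperfect** as "past"
  (*peleaba → peleábamos* is the canonical person-swap example); the
  preterite is omitted — including it would add orthographic-change
  complications (*realizar → realicé*) the regular-paradigm model cannot
  express.
* The imperfect's 1st and 3rd person singular coincide (*-aba*, *-ía*).
  Person terminations within a paradigm are therefore **not** pairwise
  distinct, and the concordance generator draws only among persons whose
  termination differs from the input's, since a swap reproducing the same
  surface form is no error.

A word is analysed by matching the longest listed termination such that
stem + class ending reconstructs an infinitive attested in the lexicon;
only when suffix matching fails is the whole word compared against the
*haber* forms (*hemos* ends in the `-er`-class `-emos`, but `her` is no
infinitive, so it resolves to *haber*). Input is lower-cased before
matching; analysis never invents an unattested infinitive.

## The six rule groups

Each group is a word-level function producing an ordered candidate list;
the first candidate that passes the real-word gate (and the distance cap)
becomes the error:

* **genre** — eleven suffix bases (`er an ad in id ic it os ari ent olo`,
  as `-ero`, `-ano`, …) give masculine/feminine pairs in both numbers;
  matched longest-first and swapped in either direction.
* **number** — vowel endings (`-o -e -a`) take `+s`, listed consonants
  (`-d -n -l -j -r`) take `+es`; plural endings (`-os -es -as`) invert
  both rules. `-es` is genuinely ambiguous (*aeronaves* strips `s`,
  *virtudes* strips `es`), so both candidates are proposed and the gate
  decides.
* **genre-number** — singular words change genre then pluralize; plural
  words singularize then change genre.
* **homophone** — `b↔v`, `ll↔y`, and the silent `h`: removed at the word
  start or after `n`/`s`, or inserted at those positions. Candidate order
  follows that listing. The gate is essential here: from *enebro* the
  first rewrite (`b→v`) yields the non-word *enevro*, and the attested
  *enhebro* (h after `n`) is what survives.
* **suggestion** — the first ranked lexicon suggestion that none of the
  other five groups could have produced from the word, so the category
  contains genuinely new confusions (*calle → callé*, not *calle →
  calles*, which is a number error).
* **concordance** — the verb's person is changed to a randomly drawn
  different person of the same tense and mood (same class; *haber* forms
  swap within their own paradigm). Draws are attempted in random order
  until one passes the gate.

Distance caps are enforced at generation time: 3 insert/delete operations
for the first five groups, 6 for concordance (a person swap like
*aba → ábamos* costs 5; *he → habéis* costs the full 6). Enforcing the cap
at the generator means the downstream correction threshold holds by
construction rather than by accident.

The sentence driver scans tokens left to right and plants the error at the
first eligible token, skipping punctuation, the number mask and a packaged
skip list of determiners, possessives, demonstratives and multi-letter
prepositions — without the skip list, the same few function words would
absorb most errors. Single-letter function words (*a*, *e*, *y*, *o*, *u*)
are deliberately not skipped: *a → ha* and *e → he* are classic homophone
errors. Rules match lower-case forms; a capitalized first letter is
preserved through the replacement, and the gate then accepts either the
cased or the lower-cased candidate. Error positions are reported 1-based,
the R convention.

## Compilation strategies and splits

Strategy 1 attempts all six groups on each sentence (fixed group order —
the per-sentence output is a set, so order carries no information;
randomness enters only through the concordance draw) and always appends one
identity record, yielding between *n* and 7 *n* records. Strategy 2 tries
the groups in a uniformly shuffled order and keeps the first success,
yielding exactly *n* records with the identity pair only as a fallback.
Both are deterministic given a seed.

Splitting labels records, not source sentences; the test split is balanced
across error types by greedy allocation (each slot goes to the
least-represented type that still has records), which achieves exact
requested sizes when possible and degrades gracefully when a type is rare.
Identity records are excluded from the test split by default — an
evaluation set should contain errors to correct. A record-level split can
place two records sharing a target sentence in different splits; that
mirrors the compilation design, and users who need grouped splits can
filter by target before splitting.

## Correction post-processing

Since errors are generated purely by character additions and deletions, the
distance between a prediction and its source is measured with the
insert/delete-only Levenshtein distance, `|a| + |b| − 2·LCS(a, b)`,
implemented as an LCS dynamic program in C++ and compared at code-point
level (`a ≠ á`). The post-processor resolves a predicted token sequence
positionally against its source: `<unknown>` tokens fall back to the source
word; a predicted token is accepted only if its distance to the source
token is **at most** the threshold (default 6). The comparison is `≤`, not
strict `<`: concordance errors reach distance exactly 6, and a strict
threshold of 6 would make them uncorrectable by design (a strict mode is
available for sensitivity analysis). One global threshold is used because
the error type of a token is unknown at inference time; the per-type caps
describe generation, not inference. When source and prediction differ in
length, alignment is positional: surplus predictions are dropped and
missing positions are filled from the source, so output length always
equals source length.

## Evaluation

Recall is corrected errors over total errors; precision is corrected
errors over corrected plus bad corrections; F0.5 = 1.25·P·R / (0.25·P + R)
weights precision twice as heavily as recall, the appropriate asymmetry
when a wrong "correction" in a clinical note is worse than a missed one.
All three are percentages; any 0/0 ratio is defined as 0.

Counting is token-level by default: an error is corrected iff the output
token at the recorded error position equals the target token, and every
output token that matches neither source nor target at its position is one
bad correction (identity records can only contribute bad corrections). A
sentence-level mode (corrected iff the whole output equals the target) is
available behind a flag, since the counting unit is a genuine modelling
choice; token-level is the default because it credits partial fixes and
charges collateral damage independently. Reports are invariant to record
order and serialize to TSV and JSON with two-decimal percentages.

## The synthetic corpus

The generator fills sentence templates (7–10 tokens, within the length
band) from a mini-lexicon of about a hundred clinical-register lemmas
expanded to roughly 900 forms: nouns and adjectives with full genre/number
paradigms whose masculine singulars carry the listed genre suffixes,
invariant modifiers, eighteen regular verbs expanded through the packaged
conjugation tables (plus participles), all *haber* forms, homophone pairs
attested on both sides (*uso/huso*, *tubo/tuvo*, *echo/hecho*,
*haya/halla*, *a/ha*, *e/he*), and function words. Slots sharing a group
agree in gender and number and verbs agree with their subject's number, so
sentences are morphologically coherent.

Closure is the load-bearing property: applying any genre/number rule to any
paradigm form, or any person swap to any generated verb form, yields
another listed form, so the real-word gate can never starve a rule group on
synthetic input. The tests verify closure directly, and a corpus of a few
hundred sentences reliably drives all six error types through a strategy-2
compilation (the suite uses 400; the acceptance runs use 10,000).

What the generator does **not** emulate: real clinical semantics and
abbreviation noise, de-identification artefacts, irregular and
orthography-changing verbs, epicene nouns and genre exceptions, diacritic
plural shifts (*lesión/lesiones*), realistic word-frequency distributions,
or capitalization errors. A green test suite on synthetic data therefore
demonstrates the machinery's correctness — gating, caps, bookkeeping,
metrics — not corpus-level realism of error rates.

Reference correctors close the loop: the oracle (returns targets) must
score R = P = F0.5 = 100, the identity corrector (returns sources) must
score R = 0, and a context bigram-vote baseline — candidates are the token
plus its rule-derived alternatives, replacement only on a strictly dominant
summed left+right bigram count, ties conservatively keep the token —
produces the non-degenerate middle ground the end-to-end tests assert.
Its characteristic failure is instructive: suggestion-based errors are
invisible to it because their corrections are not rule-derivable.

## Problem sizes and determinism

The test suite compiles a 10,000-sentence synthetic corpus once for the
distance-bound and end-to-end checks (about a minute), verifies the edit
distance exhaustively against an independently-parameterized reference on
all 1093² pairs of strings up to length 6 over a three-letter alphabet,
and spot-checks it against a breadth-first edit search. All random choices
flow through explicit seeds; there is no global, unseeded randomness
anywhere in the package.

## Known limitations

Only regular verbal morphology is modelled; the suggestion backend is the
internal lexicon suggester (an external spell checker can be substituted
behind the same contract, and its ranking may differ); accent-only
confusions are not a separate error category (they arise only incidentally,
e.g. *calle → callé* through suggestion); sentences receive at most one
error; and the evaluation assumes the corrector preserves line alignment,
with length mismatches charged as bad corrections rather than re-aligned.
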