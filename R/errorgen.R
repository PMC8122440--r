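#' Error types generated by the rule groups
#' @export
ERROR_TYPES <- c("genre", "number", "genre_number", "homophone",
                 "suggestion", "concordance")

#' Per-type caps on the insert/delete distance of a generated error
#'
#' Errors are accepted only within these distances of the original word:
#' 3 edit operations for the morphological, homophone and suggestion types,
#' 6 for subject-verb concordance (a person swap can rewrite most of the
#' termination).
#' @export
DISTANCE_CAPS <- c(genre = 3L, number = 3L, genre_number = 3L,
                   homophone = 3L, suggestion = 3L, concordance = 6L)

.rules_cfg <- function() .read_config("rules.yml")

#' Default skip list
#'
#' High-frequency Spanish determiners, possessives, demonstratives and
#' prepositions that the sentence-level error driver ignores, so that the
#' same few function words do not absorb most generated errors.
#'
#' @return Character vector of lower-case words.
#' @export
default_skip_list <- function() enc2utf8(unlist(.rules_cfg()$skip_list))

# --- candidate generators (pure; ordered candidate vectors, no gating) ----

.genre_suffix_table <- function() {
  if (is.null(.clinspell_cache$genre_tab)) {
    bases <- enc2utf8(unlist(.rules_cfg()$genre_suffix_bases))
    tab <- rbind(
      data.frame(from = paste0(bases, "o"), to = paste0(bases, "a")),
      data.frame(from = paste0(bases, "a"), to = paste0(bases, "o")),
      data.frame(from = paste0(bases, "os"), to = paste0(bases, "as")),
      data.frame(from = paste0(bases, "as"), to = paste0(bases, "os")))
    tab <- tab[order(-nchar(tab$from), tab$from), ]
    rownames(tab) <- NULL
    .clinspell_cache$genre_tab <- tab
  }
  .clinspell_cache$genre_tab
}

.genre_candidates <- function(word) {
  tab <- .genre_suffix_table()
  hit <- endsWith(word, tab$from) & nchar(word) >= nchar(tab$from)
  if (!any(hit)) return(character())
  out <- vapply(which(hit), function(i) {
    paste0(substr(word, 1L, nchar(word) - nchar(tab$from[i])), tab$to[i])
  }, character(1))
  unique(out[out != word])
}

.number_candidates <- function(word) {
  cfg <- .rules_cfg()
  vowels <- unlist(cfg$number_vowel_endings)
  cons <- unlist(cfg$number_consonant_endings)
  n <- nchar(word)
  out <- character()
  if (endsWith(word, "s") && n >= 2L) {
    # plural -> singular: drop -es after a listed consonant, -s after a vowel
    if (endsWith(word, "es") && n >= 3L &&
        substr(word, n - 2L, n - 2L) %in% cons) {
      out <- c(out, substr(word, 1L, n - 2L))
    }
    if (substr(word, n - 1L, n - 1L) %in% vowels) {
      out <- c(out, substr(word, 1L, n - 1L))
    }
  } else {
    # singular -> plural: vowel endings take +s, listed consonants +es
    last <- substr(word, n, n)
    if (last %in% vowels) out <- paste0(word, "s")
    else if (last %in% cons) out <- paste0(word, "es")
  }
  unique(out[nzchar(out) & out != word])
}

.genre_number_candidates <- function(word) {
  cfg <- .rules_cfg()
  plural_end <- unlist(cfg$number_plural_endings)
  is_plural <- any(endsWith(word, plural_end))
  first <- if (is_plural) .number_candidates(word) else
    .genre_candidates(word)
  second <- if (is_plural) .genre_candidates else .number_candidates
  out <- unlist(lapply(first, second), use.names = FALSE)
  unique(out[nzchar(out) & out != word])
}

.replace_at <- function(word, start, len, repl) {
  paste0(substr(word, 1L, start - 1L), repl,
         substr(word, start + len, nchar(word)))
}

.sub_each <- function(word, pattern, repl) {
  m <- gregexpr(pattern, word, perl = TRUE)[[1]]
  if (m[1] == -1L) return(character())
  len <- attr(m, "match.length")
  vapply(seq_along(m), function(i) .replace_at(word, m[i], len[i], repl),
         character(1))
}

.homophone_candidates <- function(word) {
  out <- c(
    .sub_each(word, "b", "v"),
    .sub_each(word, "v", "b"),
    .sub_each(word, "ll", "y"),
    .sub_each(word, "y", "ll"),
    # silent h: strip it at word start or after n/s
    if (startsWith(word, "h")) substr(word, 2L, nchar(word)),
    .sub_each(word, "(?<=[ns])h", ""),
    # and the inverse insertions
    paste0("h", word),
    .sub_each(word, "(?<=[ns])(?=[^h])", "h"),
    if (endsWith(word, "n") || endsWith(word, "s")) paste0(word, "h")
  )
  unique(out[nzchar(out) & out != word])
}

# candidate sets per group, used both by the driver and by the
# suggestion-group exclusion test
.group_candidates <- function(word, type, tables = NULL, lex = NULL) {
  switch(type,
    genre = .genre_candidates(word),
    number = .number_candidates(word),
    genre_number = .genre_number_candidates(word),
    homophone = .homophone_candidates(word),
    concordance = {
      analysis <- identify_verb(word, tables, lex)
      if (is.null(analysis)) character() else
        .concordance_forms(analysis, tables)
    },
    stop("no candidate generator for type ", type))
}

.first_attested <- function(word, candidates, lex, cap) {
  for (cand in candidates) {
    if (cand != word && lex_contains(lex, cand) &&
        indel_distance(word, cand) <= cap) {
      return(cand)
    }
  }
  NULL
}

#' Word-level real-word error rules
#'
#' Each function turns one correct word into a real-word error of its type,
#' or returns `NULL` when no rule applies:
#'
#' * `apply_genre()` swaps a matched genre suffix (e.g. `-ido`/`-ida`,
#'   `-eros`/`-eras`) for its opposite-genre counterpart, preserving number.
#' * `apply_number()` moves a word between singular and plural using the
#'   common endings (vowel `+s`, listed consonant `+es`, and their inverses).
#' * `apply_genre_number()` composes the two: singular words change genre
#'   first and are then pluralized; plural words are singularized first and
#'   then change genre.
#' * `apply_homophone()` exploits sound-identical spellings: `b`/`v` and
#'   `ll`/`y` swaps, and removal or insertion of a silent `h` at the word
#'   start or after `n`/`s`.
#'
#' When a lexicon is supplied, candidates are tried in rule order and the
#' first form attested in the lexicon (within `distance_cap` insert/delete
#' operations) is returned, making the output a real word; without a lexicon
#' the first rule-generated candidate is returned ungated.
#'
#' @param word Lower-case word.
#' @param lex Optional `lexicon` gating candidates.
#' @param distance_cap Maximum insert/delete distance (only used with `lex`).
#' @return The erroneous word, or `NULL`.
#' @examples
#' apply_genre("unido")        # "unida"
#' apply_number("aeronave")    # "aeronaves"
#' @export
apply_genre <- function(word, lex = NULL, distance_cap = DISTANCE_CAPS[["genre"]]) {
  .apply_gated(word, .genre_candidates(word), lex, distance_cap)
}

#' @rdname apply_genre
#' @export
apply_number <- function(word, lex = NULL, distance_cap = DISTANCE_CAPS[["number"]]) {
  .apply_gated(word, .number_candidates(word), lex, distance_cap)
}

#' @rdname apply_genre
#' @export
apply_genre_number <- function(word, lex = NULL,
                               distance_cap = DISTANCE_CAPS[["genre_number"]]) {
  .apply_gated(word, .genre_number_candidates(word), lex, distance_cap)
}

#' @rdname apply_genre
#' @export
apply_homophone <- function(word, lex = NULL,
                            distance_cap = DISTANCE_CAPS[["homophone"]]) {
  .apply_gated(word, .homophone_candidates(word), lex, distance_cap)
}

.apply_gated <- function(word, candidates, lex, cap) {
  if (length(candidates) == 0) return(NULL)
  if (is.null(lex)) return(candidates[[1]])
  .first_attested(word, candidates, lex, cap)
}

#' Suggestion-based real-word error
#'
#' Picks the first ranked lexicon suggestion for `word` (see [suggest()])
#' that none of the other five rule groups could have produced from it, so
#' that suggestion-based errors form their own category.
#'
#' @param word Lower-case word.
#' @param lex A `lexicon`.
#' @param tables A `conjugation_tables` (needed to exclude person-swap
#'   forms).
#' @param distance_cap Maximum insert/delete distance of the suggestion.
#' @return The erroneous word, or `NULL` if the suggestion list is exhausted.
#' @export
apply_suggestion <- function(word, lex, tables,
                             distance_cap = DISTANCE_CAPS[["suggestion"]]) {
  excl <- unique(unlist(lapply(
    c("genre", "number", "genre_number", "homophone", "concordance"),
    function(tp) .group_candidates(word, tp, tables, lex)), use.names = FALSE))
  out <- suggest(lex, word, max_distance = distance_cap, exclude = excl)
  if (length(out) == 0) NULL else out[[1]]
}

.recase_like <- function(word, model) {
  # preserve a capitalised first letter through replacement
  first <- substr(model, 1L, 1L)
  if (first != tolower(first)) {
    paste0(toupper(substr(word, 1L, 1L)), substr(word, 2L, nchar(word)))
  } else {
    word
  }
}

.is_capitalized <- function(tok) {
  grepl("^\\p{Lu}[\\p{Ll}]*$", tok, perl = TRUE)
}

#' Plant one real-word error in a sentence
#'
#' Scans the tokens left to right, skipping punctuation, the number mask and
#' skip-list words, and applies the requested rule group to each remaining
#' token. At the first token where the group yields a candidate that is
#' attested in the lexicon, differs from the original and lies within the
#' group's distance cap, the token is replaced and an error record returned.
#' Rules match lower-case forms; a capitalized first letter is preserved
#' through the replacement (the gate then accepts either the cased or the
#' lower-case form of the candidate).
#'
#' @param tokens Character vector: one normalized sentence.
#' @param type One of `ERROR_TYPES`.
#' @param lex A `lexicon`.
#' @param tables A `conjugation_tables` (used by the concordance and
#'   suggestion groups).
#' @param skip_list Lower-case words never selected as error sites.
#' @param number_mask Mask token, never selected.
#' @param distance_cap Cap on the insert/delete distance; defaults to the
#'   group's entry in [DISTANCE_CAPS].
#' @param cache Optional environment memoizing word-level outcomes of the
#'   deterministic groups across a corpus (the compilers supply one; the
#'   concordance group is never cached because its person draw is random).
#' @return A list of class `error_record` with fields `source` (erroneous
#'   tokens), `target` (the input), `error_type`, `token_index` (1-based),
#'   `original`, `error` and `distance`; or `NULL` if no token qualifies.
#' @export
generate_error <- function(tokens, type, lex, tables,
                           skip_list = default_skip_list(),
                           number_mask = NUMBER_MASK,
                           distance_cap = DISTANCE_CAPS[[type]],
                           cache = NULL) {
  type <- match.arg(type, ERROR_TYPES)
  cacheable <- !is.null(cache) && type != "concordance"
  for (i in seq_along(tokens)) {
    tok <- tokens[[i]]
    if (.is_punct_token(tok) || tok == number_mask) next
    lower <- tolower(tok)
    if (lower %in% skip_list) next
    if (tok != lower && !.is_capitalized(tok)) next  # acronyms etc.
    if (cacheable) {
      key <- paste0(type, "\r", tok)
      err <- cache[[key]]
      if (is.null(err)) {
        err <- .plant_at(lower, tok, type, lex, tables, distance_cap)
        cache[[key]] <- if (is.null(err)) "" else err
      } else if (identical(err, "")) {
        err <- NULL
      }
    } else {
      err <- .plant_at(lower, tok, type, lex, tables, distance_cap)
    }
    if (!is.null(err)) {
      source <- tokens
      source[[i]] <- err
      return(structure(
        list(source = source, target = tokens, error_type = type,
             token_index = i, original = tok, error = err,
             distance = indel_distance(tok, err)),
        class = "error_record"))
    }
  }
  NULL
}

.plant_at <- function(lower, tok, type, lex, tables, cap) {
  gate <- function(cand) {
    if (is.null(cand)) return(NULL)
    cased <- .recase_like(cand, tok)
    if (cased == tok) return(NULL)
    if (!(lex_contains(lex, cased) || lex_contains(lex, cand))) return(NULL)
    if (indel_distance(tok, cased) > cap) return(NULL)
    cased
  }
  if (type == "concordance") {
    return(gate(apply_concordance(lower, tables, lex, distance_cap = cap)))
  }
  if (type == "suggestion") {
    return(gate(apply_suggestion(lower, lex, tables, distance_cap = cap)))
  }
  for (cand in .group_candidates(lower, type)) {
    out <- gate(cand)
    if (!is.null(out) && indel_distance(lower, cand) <= cap) return(out)
  }
  NULL
}

#' @export
print.error_record <- function(x, ...) {
  cat(sprintf("<error_record> %s @%d: %s -> %s (d=%d)\n", x$error_type,
              x$token_index, x$original, x$error, x$distance))
  cat("  source:", paste(x$source, collapse = " "), "\n")
  invisible(x)
}
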