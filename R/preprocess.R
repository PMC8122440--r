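#' Punctuation retained by normalization
#'
#' Sentence punctuation kept as standalone tokens; every other
#' non-alphanumeric character is replaced by a blank before tokenization.
#' @export
RETAINED_PUNCT <- c(".", ",", ";", ":", "?", "!")

#' Default number-mask token
#' @export
NUMBER_MASK <- "NUM"

.punct_class <- "[.,;:?!]"

#' Drop unwanted corpus lines
#'
#' Removes lines matching any of a set of drop patterns (markup, metadata,
#' header/footer strings) before sentence splitting. Patterns may be given as
#' regular expressions or as predicate functions taking a line and returning
#' a logical.
#'
#' @param lines Character vector of raw corpus lines.
#' @param drop_patterns Character vector of regular expressions, or a list of
#'   predicate functions; a line matching any pattern is removed.
#' @return Character vector of retained lines, order preserved.
#' @examples
#' clean_corpus_lines(c("<doc id=1>", "El paciente mejora."), "^<.*>$")
#' @export
clean_corpus_lines <- function(lines, drop_patterns = character()) {
  if (length(lines) == 0) return(character())
  drop <- rep(FALSE, length(lines))
  if (is.character(drop_patterns)) {
    for (p in drop_patterns) drop <- drop | grepl(p, lines, perl = TRUE)
  } else {
    for (p in drop_patterns) {
      stopifnot(is.function(p))
      drop <- drop | vapply(lines, p, logical(1), USE.NAMES = FALSE)
    }
  }
  lines[!drop]
}

#' Split raw text into sentences
#'
#' Rule-based sentence splitter: a sentence boundary is a terminator
#' (`.`, `?` or `!`) followed by whitespace and an upper-case letter or digit.
#' Sentence-leading semicolons (an artefact of splitting on semicolon-joined
#' clauses) are stripped, as is boundary whitespace. Empty sentences are
#' dropped.
#'
#' @param text Character scalar (may contain newlines) or vector of lines.
#' @return Character vector of sentence strings.
#' @examples
#' split_sentences("Paciente estable. Se procede al alta.")
#' @export
split_sentences <- function(text) {
  text <- paste(enc2utf8(as.character(text)), collapse = "\n")
  if (!nzchar(trimws(text))) return(character())
  # keep the terminator with its sentence; break before space+capital/digit
  pieces <- strsplit(text, "(?<=[.?!])\\s+(?=[\\p{Lu}0-9])", perl = TRUE)[[1]]
  pieces <- unlist(strsplit(pieces, "\n", fixed = TRUE), use.names = FALSE)
  pieces <- sub("^[;\\s]+", "", pieces, perl = TRUE)
  pieces <- trimws(pieces)
  pieces[nzchar(pieces)]
}

#' Normalize a sentence into tokens
#'
#' Applies, in order: masking of every maximal digit run by a constant token;
#' replacement of all characters that are not letters, digits or retained
#' sentence punctuation by a blank; separation of retained punctuation into
#' standalone tokens. Letter case is left untouched (a lower-cased sentence
#' start is itself a real-word error and must survive preprocessing).
#'
#' @param text Sentence as a character scalar, or an already-tokenized
#'   character vector (tokens are re-joined and re-normalized, which makes the
#'   function idempotent).
#' @param number_mask Token substituted for each digit run. Must contain
#'   letters only.
#' @return Character vector of tokens.
#' @examples
#' normalize_sentence("El paciente tiene 45 años.")
#' @export
normalize_sentence <- function(text, number_mask = NUMBER_MASK) {
  stopifnot(length(number_mask) == 1L,
            grepl("^\\p{L}+$", number_mask, perl = TRUE))
  s <- paste(enc2utf8(as.character(text)), collapse = " ")
  s <- gsub("[0-9]+", paste0(" ", number_mask, " "), s, perl = TRUE)
  s <- gsub("[^\\p{L}0-9.,;:?!\\s]", " ", s, perl = TRUE)
  s <- gsub(paste0("(", .punct_class, ")"), " \\1 ", s, perl = TRUE)
  toks <- strsplit(trimws(s), "\\s+", perl = TRUE)[[1]]
  toks[nzchar(toks)]
}

#' Filter sentences by token count
#'
#' Retains sentences strictly longer than `min_tokens` and no longer than
#' `max_tokens`. For small domain corpora the filter can be disabled, in which
#' case the input is returned unchanged.
#'
#' @param sentences List of token vectors.
#' @param min_tokens,max_tokens Length bounds; a sentence is kept when
#'   `min_tokens < length <= max_tokens`.
#' @param enabled When `FALSE`, no filtering is applied.
#' @return List of retained token vectors.
#' @export
length_filter <- function(sentences, min_tokens = 5L, max_tokens = 40L,
                          enabled = TRUE) {
  stopifnot(min_tokens <= max_tokens)
  if (!enabled) return(sentences)
  n <- lengths(sentences)
  sentences[n > min_tokens & n <= max_tokens]
}

#' Preprocess a raw corpus end to end
#'
#' Cleans lines, splits sentences, normalizes each into tokens and applies the
#' length filter.
#'
#' @inheritParams clean_corpus_lines
#' @inheritParams normalize_sentence
#' @inheritParams length_filter
#' @param length_filtered Whether to apply the token-count filter.
#' @return List of token vectors.
#' @export
preprocess_corpus <- function(lines, drop_patterns = character(),
                              number_mask = NUMBER_MASK,
                              min_tokens = 5L, max_tokens = 40L,
                              length_filtered = TRUE) {
  kept <- clean_corpus_lines(lines, drop_patterns)
  sents <- split_sentences(kept)
  toks <- lapply(sents, normalize_sentence, number_mask = number_mask)
  toks <- toks[lengths(toks) > 0]
  length_filter(toks, min_tokens, max_tokens, enabled = length_filtered)
}

.is_punct_token <- function(tok) tok %in% RETAINED_PUNCT
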