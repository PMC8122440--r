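#' Construct a lexicon from words and counts
#'
#' A lexicon is the corpus-derived dictionary that defines real-word
#' membership: a generated candidate is only accepted as a real-word error if
#' it is attested here. Membership is exact and case-sensitive.
#'
#' @param words Character vector of word forms.
#' @param counts Integer vector of occurrence counts (recycled if scalar).
#' @param min_count Minimum count; entries below it are dropped.
#' @return An object of class `lexicon`.
#' @export
new_lexicon <- function(words = character(), counts = integer(),
                        min_count = 1L) {
  stopifnot(min_count >= 1)
  words <- enc2utf8(as.character(words))
  counts <- as.integer(rep_len(counts, length(words)))
  if (anyDuplicated(words)) {
    counts <- vapply(split(counts, words), sum, integer(1))
    words <- names(counts)
    counts <- unname(counts)
  }
  keep <- counts >= min_count
  words <- words[keep]
  counts <- counts[keep]
  o <- order(words, method = "radix")
  words <- words[o]
  counts <- counts[o]
  env <- new.env(parent = emptyenv(), size = max(29L, length(words)))
  for (i in seq_along(words)) assign(words[i], counts[i], envir = env)
  structure(
    list(words = words, counts = counts,
         codes = lapply(words, utf8ToInt),
         env = env, min_count = as.integer(min_count)),
    class = "lexicon"
  )
}

#' Build a lexicon from a tokenized corpus
#'
#' Counts every token in the corpus except punctuation and the number-mask
#' token, and keeps the words occurring at least `min_count` times.
#'
#' @param sentences List of token vectors (normalized sentences).
#' @param min_count Occurrence threshold.
#' @param number_mask Mask token to exclude from counting.
#' @return A `lexicon`.
#' @export
build_lexicon <- function(sentences, min_count = 1L,
                          number_mask = NUMBER_MASK) {
  toks <- unlist(sentences, use.names = FALSE)
  toks <- toks[!(toks %in% RETAINED_PUNCT) & toks != number_mask]
  if (length(toks) == 0) return(new_lexicon(min_count = min_count))
  tab <- table(toks)
  new_lexicon(names(tab), as.integer(tab), min_count = min_count)
}

#' @export
print.lexicon <- function(x, ...) {
  cat("<lexicon>", length(x$words), "entries, min_count =", x$min_count, "\n")
  invisible(x)
}

#' @export
length.lexicon <- function(x) length(x$words)

#' @export
as.data.frame.lexicon <- function(x, ...) {
  data.frame(word = x$words, count = x$counts, stringsAsFactors = FALSE)
}

#' Lexicon membership and counts
#'
#' @param lex A `lexicon`.
#' @param words Character vector of words to query (case-sensitive).
#' @return `lex_contains`: logical vector; `lex_count`: integer vector
#'   (0 for absent words).
#' @export
lex_contains <- function(lex, words) {
  lex_count(lex, words) > 0L
}

#' @rdname lex_contains
#' @export
lex_count <- function(lex, words) {
  if (length(words) == 0) return(integer())
  unlist(mget(enc2utf8(as.character(words)), envir = lex$env,
              ifnotfound = 0L), use.names = FALSE)
}

#' Rank spelling suggestions from the lexicon
#'
#' Returns lexicon entries within `max_distance` insert/delete edit
#' operations of `word`, excluding the word itself and any explicitly
#' excluded forms, ranked by distance (ascending), then corpus frequency
#' (descending), then byte-wise lexicographic order. The ranking is a total
#' order, so output is deterministic for a fixed lexicon.
#'
#' @param lex A `lexicon`.
#' @param word Word to suggest alternatives for.
#' @param max_distance Maximum insert/delete distance.
#' @param exclude Character vector of forms never to propose (used by the
#'   suggestion-based error generator to avoid reproducing the morphological
#'   error types).
#' @return Character vector of suggestions, best first (possibly empty).
#' @export
suggest <- function(lex, word, max_distance = 3L, exclude = character()) {
  stopifnot(nzchar(word))
  if (length(lex$words) == 0) return(character())
  d <- .indel_to_codes(word, lex$codes, cap = max_distance)
  ok <- d <= max_distance & lex$words != word
  if (length(exclude)) ok <- ok & !(lex$words %in% exclude)
  if (!any(ok)) return(character())
  w <- lex$words[ok]
  w[order(d[ok], -lex$counts[ok], w, method = "radix")]
}

#' Read and write lexicons as two-column TSV
#'
#' The on-disk format is `word<TAB>count`, one entry per line, UTF-8.
#'
#' @param lex A `lexicon`.
#' @param path File path.
#' @param min_count Threshold applied on read.
#' @return `write_lexicon` returns `path` invisibly; `read_lexicon` returns a
#'   `lexicon`.
#' @export
write_lexicon <- function(lex, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(lex$words, lex$counts, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_lexicon
#' @export
read_lexicon <- function(path, min_count = 1L) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(new_lexicon(min_count = min_count))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) stop("malformed lexicon line ", bad[1], " in ", path)
  new_lexicon(vapply(parts, `[[`, character(1), 1L),
              as.integer(vapply(parts, `[[`, character(1), 2L)),
              min_count = min_count)
}
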