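#' Insert/delete-only edit distance
#'
#' Minimum number of single-character insertions and deletions transforming
#' `a` into `b`. Substitutions are not elementary operations (one substitution
#' counts as a deletion plus an insertion), so the distance equals
#' `nchar(a) + nchar(b) - 2 * LCS(a, b)`. Real-word errors are produced by
#' adding and deleting characters, which is why corrector output is gated on
#' this distance rather than on the full Levenshtein distance. Comparison is
#' at code-point level: accented characters are distinct from their bare
#' counterparts (`"a" != "á"`).
#'
#' @param a,b Character vectors, recycled to a common length.
#' @return Integer vector of distances.
#' @examples
#' indel_distance("unido", "unida")       # 2
#' indel_distance("peleaba", "peleábamos") # 5
#' @export
indel_distance <- function(a, b) {
  n <- max(length(a), length(b))
  if (n == 0L) return(integer())
  a <- rep_len(enc2utf8(as.character(a)), n)
  b <- rep_len(enc2utf8(as.character(b)), n)
  indel_dist_pairs(lapply(a, utf8ToInt), lapply(b, utf8ToInt))
}

# distances from one word to a list of precomputed code-point vectors,
# values above cap reported as cap + 1
.indel_to_codes <- function(word, codes, cap = -1L) {
  indel_dist_one_to_many(utf8ToInt(enc2utf8(word)), codes, as.integer(cap))
}

#' Post-process corrector predictions
#'
#' Resolves a predicted token sequence against its source sentence:
#' * a predicted `unknown_token` (emitted by a sequence model for
#'   out-of-vocabulary words) is replaced by the source token;
#' * a predicted token whose insert/delete edit distance to the source token
#'   exceeds `threshold` is rejected and the source token kept — large edits
#'   are far more likely to be hallucinations than corrections;
#' * positions beyond the prediction's length are filled from the source, and
#'   surplus predicted tokens are dropped, so the output always has the
#'   source's length.
#'
#' @param source Character vector of source (possibly erroneous) tokens.
#' @param predicted Character vector of predicted tokens.
#' @param threshold Maximum accepted distance; a prediction at distance
#'   `<= threshold` (or `< threshold` in strict mode) replaces the source
#'   token. The default 6 admits every error type the generators produce,
#'   subject-verb concordance included.
#' @param unknown_token Literal the corrector emits for unknown words.
#' @param strict When `TRUE`, use a strict `<` comparison against the
#'   threshold instead of `<=`.
#' @return Character vector of tokens, same length as `source`.
#' @export
resolve_prediction <- function(source, predicted, threshold = 6L,
                               unknown_token = "<unknown>", strict = FALSE) {
  stopifnot(threshold >= 0)
  n <- length(source)
  out <- source
  m <- min(n, length(predicted))
  if (m > 0L) {
    pred <- predicted[seq_len(m)]
    src <- source[seq_len(m)]
    consider <- pred != unknown_token & pred != src
    if (any(consider)) {
      d <- indel_distance(src[consider], pred[consider])
      ok <- if (strict) d < threshold else d <= threshold
      idx <- which(consider)[ok]
      out[idx] <- pred[idx]
    }
  }
  out
}
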