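#' F0.5 score
#'
#' Precision-weighted harmonic mean `1.25 * P * R / (0.25 * P + R)`, the
#' standard figure of merit for error correction, where proposing a wrong
#' correction is costlier than missing one. Inputs and output are
#' percentages; a zero denominator yields 0.
#'
#' @param recall,precision Percentages in `[0, 100]`.
#' @return F0.5 as a percentage.
#' @examples
#' f05_score(50.92, 69.79)
#' @export
f05_score <- function(recall, precision) {
  den <- 0.25 * precision + recall
  ifelse(den > 0, 1.25 * precision * recall / den, 0)
}

#' Recall, precision and F0.5 from outcome counts
#'
#' Recall is the fraction of planted errors whose token was restored to the
#' target word; precision relates restored errors to all changes the
#' corrector made, counting as bad corrections the output tokens that match
#' neither the source nor the target at their position. Any 0/0 ratio is
#' defined as 0.
#'
#' @param total_errors Number of planted errors.
#' @param corrected Number of errors whose position holds the target token.
#' @param bad_corrections Number of output tokens differing from both source
#'   and target.
#' @return Named numeric vector with `recall`, `precision`, `f05`
#'   (percentages).
#' @export
compute_metrics <- function(total_errors, corrected, bad_corrections) {
  stopifnot(corrected <= total_errors, corrected >= 0, bad_corrections >= 0)
  r <- if (total_errors > 0) 100 * corrected / total_errors else 0
  den <- corrected + bad_corrections
  p <- if (den > 0) 100 * corrected / den else 0
  c(recall = r, precision = p, f05 = f05_score(r, p))
}

.tokenize_outputs <- function(outputs) {
  if (is.character(outputs)) sentence_tokens(outputs) else outputs
}

.outcome_one <- function(src, tgt, out, token_index, is_identity,
                         sentence_level = FALSE) {
  m <- min(length(src), length(out))
  extra <- abs(length(src) - length(out))
  common <- seq_len(m)
  bad <- sum(out[common] != src[common] & out[common] != tgt[common]) + extra
  corrected <- 0L
  if (!is_identity) {
    if (sentence_level) {
      corrected <- as.integer(length(out) == length(tgt) &&
                                all(out == tgt))
    } else {
      corrected <- as.integer(token_index <= m &&
                                out[token_index] == tgt[token_index])
    }
  }
  c(corrected = corrected, bad = bad)
}

#' Count correction outcomes
#'
#' Compares corrector output against a parallel dataset, per error type and
#' overall. An error counts as corrected when the output token at the
#' recorded error position equals the target token (token-level default), or
#' when the whole output sentence equals the target (`sentence_level =
#' TRUE`). Every output token matching neither source nor target counts as
#' one bad correction; identity records contribute bad corrections only.
#'
#' @param ds A `parallel_dataset`.
#' @param outputs Corrector output: a list of token vectors or a character
#'   vector of space-joined sentences, line-aligned with `ds`.
#' @param sentence_level Use whole-sentence equality as the correction
#'   criterion.
#' @return Data frame with one row per error type present plus `identity`
#'   (if present) and `overall`, columns `error_type`, `total_errors`,
#'   `corrected`, `bad_corrections`.
#' @export
classify_outcomes <- function(ds, outputs, sentence_level = FALSE) {
  outputs <- .tokenize_outputs(outputs)
  if (length(outputs) != nrow(ds)) {
    stop("got ", length(outputs), " output sentences for ", nrow(ds),
         " records")
  }
  src <- sentence_tokens(ds$source)
  tgt <- sentence_tokens(ds$target)
  types <- ds$error_type
  res <- vapply(seq_len(nrow(ds)), function(i) {
    .outcome_one(src[[i]], tgt[[i]], outputs[[i]], ds$token_index[i],
                 types[i] == "identity", sentence_level)
  }, c(corrected = 0L, bad = 0L))
  agg <- function(sel) {
    c(total_errors = sum(types[sel] != "identity"),
      corrected = sum(res["corrected", sel]),
      bad_corrections = sum(res["bad", sel]))
  }
  lev <- c(intersect(c(ERROR_TYPES, "identity"), unique(types)))
  rows <- lapply(lev, function(tp) agg(types == tp))
  rows <- c(rows, list(agg(rep(TRUE, length(types)))))
  out <- as.data.frame(do.call(rbind, rows))
  out$error_type <- c(lev, "overall")
  out[, c("error_type", "total_errors", "corrected", "bad_corrections")]
}

#' Score corrector output
#'
#' Aggregates [classify_outcomes()] and computes recall, precision and F0.5
#' per error type and overall.
#'
#' @inheritParams classify_outcomes
#' @return Data frame of class `eval_report` with columns `error_type`,
#'   `total_errors`, `corrected`, `bad_corrections`, `recall`, `precision`,
#'   `f05` (percentages, full precision; the print method rounds to two
#'   decimals as is customary).
#' @export
evaluate_corrections <- function(ds, outputs, sentence_level = FALSE) {
  counts <- classify_outcomes(ds, outputs, sentence_level)
  mets <- t(vapply(seq_len(nrow(counts)), function(i) {
    compute_metrics(counts$total_errors[i], counts$corrected[i],
                    counts$bad_corrections[i])
  }, c(recall = 0, precision = 0, f05 = 0)))
  out <- cbind(counts, as.data.frame(mets))
  class(out) <- c("eval_report", "data.frame")
  out
}

#' @export
print.eval_report <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  y$recall <- round(y$recall, digits)
  y$precision <- round(y$precision, digits)
  y$f05 <- round(y$f05, digits)
  print(y, row.names = FALSE)
  cat("(0/0 ratios reported as 0)\n")
  invisible(x)
}

#' Write an evaluation report
#'
#' @param report An `eval_report`.
#' @param path Output file.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(report)
  for (col in c("recall", "precision", "f05")) df[[col]] <- round(df[[col]], 2)
  if (format == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA)
  }
  invisible(path)
}
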