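#' Parallel dataset construction
#'
#' A parallel dataset is an ordered collection of (source, target) sentence
#' pairs: the source side carries at most one planted real-word error, the
#' target side is the original correct sentence. Identity pairs (source =
#' target) augment the data. It is represented as a data frame of class
#' `parallel_dataset` with columns `id`, `split`, `error_type` (one of
#' [ERROR_TYPES] or `"identity"`), `token_index` (1-based, `NA` for
#' identity), `original`, `error`, `distance` and the space-joined `source`
#' and `target` sentences.
#'
#' @name parallel_dataset
NULL

.new_dataset <- function(rows) {
  if (length(rows) == 0) {
    df <- data.frame(id = integer(), split = character(),
                     error_type = character(), token_index = integer(),
                     original = character(), error = character(),
                     distance = integer(), source = character(),
                     target = character(), stringsAsFactors = FALSE)
  } else {
    df <- do.call(rbind, rows)
    df$id <- seq_len(nrow(df))
  }
  rownames(df) <- NULL
  class(df) <- c("parallel_dataset", "data.frame")
  df
}

.record_row <- function(rec) {
  data.frame(id = NA_integer_, split = NA_character_,
             error_type = rec$error_type, token_index = rec$token_index,
             original = rec$original, error = rec$error,
             distance = rec$distance,
             source = paste(rec$source, collapse = " "),
             target = paste(rec$target, collapse = " "),
             stringsAsFactors = FALSE)
}

.identity_row <- function(tokens) {
  s <- paste(tokens, collapse = " ")
  data.frame(id = NA_integer_, split = NA_character_,
             error_type = "identity", token_index = NA_integer_,
             original = NA_character_, error = NA_character_,
             distance = NA_integer_, source = s, target = s,
             stringsAsFactors = FALSE)
}

#' Tokenize dataset sentences
#'
#' @param x Character vector of space-joined sentences.
#' @return List of token vectors.
#' @export
sentence_tokens <- function(x) strsplit(x, " ", fixed = TRUE)

#' Compile a parallel dataset: one record per error type per sentence
#'
#' For each corpus sentence, each of the six rule groups is attempted once
#' (in a fixed group order; randomness enters only through the concordance
#' person draw), emitting up to six single-error records, and the correct
#' sentence is always appended as an identity record, which augments the
#' training data.
#'
#' @param corpus List of token vectors (normalized sentences).
#' @param lex A `lexicon`.
#' @param tables A `conjugation_tables`.
#' @param skip_list Words ignored by the error driver.
#' @param seed Optional integer seed making the compilation reproducible.
#' @param number_mask Mask token.
#' @return A `parallel_dataset` with between `n` and `7 n` records for an
#'   `n`-sentence corpus, in corpus order.
#' @export
compile_strategy1 <- function(corpus, lex, tables,
                              skip_list = default_skip_list(), seed = NULL,
                              number_mask = NUMBER_MASK) {
  if (!is.null(seed)) set.seed(seed)
  cache <- new.env(parent = emptyenv())
  rows <- vector("list", length(corpus) * 7L)
  k <- 0L
  for (tokens in corpus) {
    for (type in ERROR_TYPES) {
      rec <- generate_error(tokens, type, lex, tables, skip_list,
                            number_mask, cache = cache)
      if (!is.null(rec)) {
        k <- k + 1L
        rows[[k]] <- .record_row(rec)
      }
    }
    k <- k + 1L
    rows[[k]] <- .identity_row(tokens)
  }
  .new_dataset(rows[seq_len(k)])
}

#' Compile a parallel dataset: exactly one record per sentence
#'
#' For each corpus sentence the six rule groups are tried in a uniformly
#' shuffled order and the first group that succeeds contributes the (single)
#' record, which balances error types across the dataset; the identity
#' record is used only when no group can generate an error.
#'
#' @inheritParams compile_strategy1
#' @return A `parallel_dataset` with exactly one record per input sentence,
#'   in corpus order.
#' @export
compile_strategy2 <- function(corpus, lex, tables,
                              skip_list = default_skip_list(), seed = NULL,
                              number_mask = NUMBER_MASK) {
  if (!is.null(seed)) set.seed(seed)
  cache <- new.env(parent = emptyenv())
  rows <- vector("list", length(corpus))
  for (s in seq_along(corpus)) {
    tokens <- corpus[[s]]
    row <- NULL
    for (type in sample(ERROR_TYPES)) {
      rec <- generate_error(tokens, type, lex, tables, skip_list,
                            number_mask, cache = cache)
      if (!is.null(rec)) {
        row <- .record_row(rec)
        break
      }
    }
    rows[[s]] <- if (is.null(row)) .identity_row(tokens) else row
  }
  .new_dataset(rows)
}

#' Assign train/validation/test split labels
#'
#' Labels `n_test` records as test and `n_validation` as validation, the
#' remainder as train. The test split is balanced across error types when
#' feasible: test slots are allocated greedily to the error type with the
#' most unallocated records, then filled by sampling without replacement
#' within each type. Identity records are excluded from the test split by
#' default (the evaluation set should contain errors to correct).
#'
#' @param ds A `parallel_dataset`.
#' @param n_validation,n_test Requested split sizes.
#' @param seed Optional integer seed.
#' @param test_include_identity Allow identity records in the test split.
#' @return The dataset with its `split` column filled.
#' @export
split_dataset <- function(ds, n_validation, n_test, seed = NULL,
                          test_include_identity = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ds)
  if (n_validation + n_test > n) {
    stop("requested validation (", n_validation, ") + test (", n_test,
         ") sizes exceed the ", n, " available records")
  }
  eligible <- if (test_include_identity) seq_len(n) else
    which(ds$error_type != "identity")
  if (length(eligible) < n_test) {
    stop("requested test size ", n_test, " exceeds the ", length(eligible),
         " eligible records")
  }
  by_type <- split(eligible, ds$error_type[eligible])
  remaining <- lengths(by_type)
  quota <- setNames(integer(length(by_type)), names(by_type))
  for (k in seq_len(n_test)) {
    # balance: always extend the least-represented type that still has
    # records; ties broken by (alphabetical) type order
    open <- which(remaining > 0L)
    pick <- open[which.min(quota[open])]
    quota[pick] <- quota[pick] + 1L
    remaining[pick] <- remaining[pick] - 1L
  }
  test_idx <- unlist(lapply(names(by_type), function(tp) {
    idx <- by_type[[tp]]
    if (quota[tp] == length(idx)) idx else sample(idx, quota[tp])
  }), use.names = FALSE)
  rest <- setdiff(seq_len(n), test_idx)
  val_idx <- if (n_validation > 0) sample(rest, n_validation) else integer()
  ds$split <- "train"
  ds$split[val_idx] <- "validation"
  ds$split[test_idx] <- "test"
  ds
}

#' Write and read a parallel dataset on disk
#'
#' The on-disk representation is the line-parallel text dialect consumed by
#' neural-translation toolkits: a source file and a target file with one
#' space-tokenized sentence per line, plus a JSON-lines metadata file with
#' fields `id`, `split`, `error_type`, `token_index`, `original`, `error`
#' and `distance` per record.
#'
#' @param ds A `parallel_dataset`.
#' @param source_path,target_path,meta_path File paths; `meta_path` may be
#'   `NULL` to write sentence files only.
#' @return `write_parallel` returns the paths invisibly; `read_parallel`
#'   returns a `parallel_dataset`.
#' @export
write_parallel <- function(ds, source_path, target_path, meta_path = NULL) {
  .write_utf8 <- function(lines, path) {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    if (length(lines)) writeLines(lines, con) else cat("", file = con)
  }
  .write_utf8(ds$source, source_path)
  .write_utf8(ds$target, target_path)
  if (!is.null(meta_path)) {
    meta <- ds[, c("id", "split", "error_type", "token_index", "original",
                   "error", "distance")]
    lines <- vapply(seq_len(nrow(meta)), function(i) {
      jsonlite::toJSON(as.list(meta[i, ]), auto_unbox = TRUE, null = "null",
                       na = "null")
    }, character(1))
    .write_utf8(lines, meta_path)
  }
  invisible(c(source = source_path, target = target_path))
}

#' @rdname write_parallel
#' @export
read_parallel <- function(source_path, target_path, meta_path = NULL) {
  src <- readLines(source_path, encoding = "UTF-8")
  tgt <- readLines(target_path, encoding = "UTF-8")
  if (length(src) != length(tgt)) {
    stop("source/target line counts differ: ", length(src), " vs ",
         length(tgt), " (first divergence at line ",
         min(length(src), length(tgt)) + 1L, ")")
  }
  n <- length(src)
  df <- data.frame(id = seq_len(n), split = rep(NA_character_, n),
                   error_type = rep(NA_character_, n),
                   token_index = rep(NA_integer_, n),
                   original = rep(NA_character_, n),
                   error = rep(NA_character_, n),
                   distance = rep(NA_integer_, n), source = src,
                   target = tgt, stringsAsFactors = FALSE)
  if (!is.null(meta_path)) {
    lines <- readLines(meta_path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    if (length(lines) != n) {
      stop("metadata has ", length(lines), " records for ", n, " sentences")
    }
    for (i in seq_len(n)) {
      m <- jsonlite::fromJSON(lines[i])
      df$split[i] <- if (is.null(m$split)) NA_character_ else m$split
      df$error_type[i] <- if (is.null(m$error_type)) NA_character_ else
        m$error_type
      df$token_index[i] <- if (is.null(m$token_index)) NA_integer_ else
        as.integer(m$token_index)
      df$original[i] <- if (is.null(m$original)) NA_character_ else
        m$original
      df$error[i] <- if (is.null(m$error)) NA_character_ else m$error
      df$distance[i] <- if (is.null(m$distance)) NA_integer_ else
        as.integer(m$distance)
    }
  } else if (n > 0) {
    df$error_type <- ifelse(df$source == df$target, "identity",
                            NA_character_)
  }
  class(df) <- c("parallel_dataset", "data.frame")
  df
}

#' @export
print.parallel_dataset <- function(x, ...) {
  cat("<parallel_dataset>", nrow(x), "records\n")
  if (nrow(x)) print(table(x$error_type))
  invisible(x)
}
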