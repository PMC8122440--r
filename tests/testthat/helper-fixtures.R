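# Shared fixtures and independent oracles.

# Fixture lexicon attesting the error forms of the worked rule examples.
worked_examples_lexicon <- function() {
  new_lexicon(
    c("unida", "traicioneros", "aeronaves", "virtud", "sinuosa",
      "abandonadas", "ha", "enhebro", "huso", "calle", "callé", "calles",
      "agravio", "agrado", "masa", "amas", "llevar", "llevas", "pelear",
      "peleábamos"),
    counts = 1L)
}

# Breadth-first edit search over strings: expand by single-character
# deletions and by insertions of characters drawn from the two words, level
# by level, until the target is reached. Independent of the DP route.
# States longer than max(nchar(a), nchar(b)) are pruned: an optimal
# delete-first path never exceeds that length.
bfs_indel <- function(a, b) {
  if (identical(a, b)) return(0L)
  alphabet <- unique(strsplit(paste0(a, b), "")[[1]])
  max_len <- max(nchar(a), nchar(b))
  expand <- function(s) {
    n <- nchar(s)
    out <- character()
    if (n > 0) {
      out <- vapply(seq_len(n), function(i) {
        paste0(substr(s, 1, i - 1), substr(s, i + 1, n))
      }, character(1))
    }
    if (n < max_len) {
      for (ch in alphabet) {
        out <- c(out, vapply(seq_len(n + 1), function(i) {
          paste0(substr(s, 1, i - 1), ch, substr(s, i, n))
        }, character(1)))
      }
    }
    unique(out)
  }
  seen <- new.env(parent = emptyenv())
  key <- function(s) paste0(".", s)  # "" is not a legal variable name
  assign(key(a), TRUE, envir = seen)
  frontier <- a
  for (depth in seq_len(2L * max_len)) {
    nxt <- unique(unlist(lapply(frontier, expand), use.names = FALSE))
    nxt <- nxt[!vapply(key(nxt), exists, logical(1), envir = seen)]
    if (b %in% nxt) return(depth)
    for (s in nxt) assign(key(s), TRUE, envir = seen)
    frontier <- nxt
    if (length(frontier) == 0) break
  }
  stop("BFS failed for ", a, " / ", b)
}

# Reference insert/delete distance through utils::adist with a substitution
# cost of 2 (a substitution is then exactly one deletion plus one insertion).
adist_indel <- function(a, b) {
  utils::adist(a, b,
               costs = list(insertions = 1, deletions = 1, substitutions = 2))
}

# One compilation of the full-size synthetic corpus, shared (memoized)
# across the acceptance checks that measure it.
.accept_memo <- new.env(parent = emptyenv())
acceptance_compilation <- function() {
  if (is.null(.accept_memo$res)) {
    tables <- load_conjugations()
    corpus <- generate_corpus(10000, seed = 20240101, tables = tables)
    lex <- synthetic_lexicon(corpus, tables)
    ds1 <- compile_strategy1(corpus, lex, tables, seed = 11)
    .accept_memo$res <- list(tables = tables, corpus = corpus, lex = lex,
                             ds1 = ds1)
  }
  .accept_memo$res
}
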