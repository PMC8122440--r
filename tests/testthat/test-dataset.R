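tb <- load_conjugations()

# a sentence crafted so that every group can fire: adjective with a genre
# suffix, plural noun, homophone bearer, verb, and suggestion material
all_groups_corpus <- function() {
  list(c("El", "médico", "usa", "el", "tubo", "en", "casos", "unidos", "."))
}

all_groups_lexicon <- function() {
  synthetic_lexicon(all_groups_corpus())
}

test_that("strategy 1 emits one record per applicable group plus identity", {
  lex <- all_groups_lexicon()
  ds <- compile_strategy1(all_groups_corpus(), lex, tb, seed = 4)
  expect_equal(nrow(ds), 7L)
  expect_setequal(ds$error_type, c(ERROR_TYPES, "identity"))
  # identity record appended after the errors, with source = target
  expect_equal(ds$error_type[7], "identity")
  expect_equal(ds$source[7], ds$target[7])
  # a sentence where nothing fires yields the identity record alone
  inert <- list(c("El", "de", "la", "."))
  ds0 <- compile_strategy1(inert, lex, tb, seed = 4)
  expect_equal(ds0$error_type, "identity")
  # empty corpus -> empty dataset
  expect_equal(nrow(compile_strategy1(list(), lex, tb)), 0L)
})

test_that("strategy 2 emits exactly one record per sentence", {
  corpus <- generate_corpus(120, seed = 5, tables = tb)
  lex <- synthetic_lexicon(corpus, tb)
  ds <- compile_strategy2(corpus, lex, tb, seed = 6)
  expect_equal(nrow(ds), length(corpus))
  expect_equal(ds$target, vapply(corpus, paste, "", collapse = " "))
  inert <- list(c("El", "de", "la", "."), c("La", "de", "el", "."))
  ds0 <- compile_strategy2(inert, lex, tb, seed = 6)
  expect_equal(ds0$error_type, c("identity", "identity"))
})

test_that("compilations are deterministic under a fixed seed and bounded in size", {
  corpus <- generate_corpus(60, seed = 10, tables = tb)
  lex <- synthetic_lexicon(corpus, tb)
  a <- compile_strategy1(corpus, lex, tb, seed = 42)
  b <- compile_strategy1(corpus, lex, tb, seed = 42)
  expect_identical(a, b)
  expect_gte(nrow(a), length(corpus))
  expect_lte(nrow(a), 7L * length(corpus))
  a2 <- compile_strategy2(corpus, lex, tb, seed = 42)
  b2 <- compile_strategy2(corpus, lex, tb, seed = 42)
  expect_identical(a2, b2)
})

test_that("non-identity records validate as error records", {
  corpus <- generate_corpus(80, seed = 12, tables = tb)
  lex <- synthetic_lexicon(corpus, tb)
  ds <- compile_strategy2(corpus, lex, tb, seed = 13)
  err <- ds[ds$error_type != "identity", ]
  src <- sentence_tokens(err$source)
  tgt <- sentence_tokens(err$target)
  for (i in seq_len(nrow(err))) {
    expect_equal(length(src[[i]]), length(tgt[[i]]))
    expect_equal(which(src[[i]] != tgt[[i]]), err$token_index[i])
    expect_equal(src[[i]][err$token_index[i]], err$error[i])
    expect_equal(tgt[[i]][err$token_index[i]], err$original[i])
    expect_lte(err$distance[i], DISTANCE_CAPS[[err$error_type[i]]])
  }
})

test_that("split_dataset sizes, balance and failure modes", {
  corpus <- generate_corpus(100, seed = 21, tables = tb)
  lex <- synthetic_lexicon(corpus, tb)
  ds <- compile_strategy2(corpus, lex, tb, seed = 22)
  out <- split_dataset(ds, n_validation = 10, n_test = 10, seed = 23,
                       test_include_identity = TRUE)
  expect_equal(as.integer(table(out$split)[c("train", "validation", "test")]),
               c(80L, 10L, 10L))
  # balanced test split on a larger compilation
  big <- compile_strategy1(generate_corpus(300, seed = 24, tables = tb),
                           lex, tb, seed = 25)
  bt <- split_dataset(big, n_validation = 0, n_test = 60, seed = 26)
  per_type <- table(bt$error_type[bt$split == "test"])
  expect_equal(as.integer(per_type[ERROR_TYPES]), rep(10L, 6))
  expect_false("identity" %in% names(per_type))
  expect_error(split_dataset(ds, 0, nrow(ds) + 1), "exceed")
})

test_that("parallel files round-trip and misalignment is caught", {
  corpus <- generate_corpus(30, seed = 31, tables = tb)
  lex <- synthetic_lexicon(corpus, tb)
  ds <- compile_strategy2(corpus, lex, tb, seed = 32)
  ds <- split_dataset(ds, 5, 5, seed = 33, test_include_identity = TRUE)
  dir <- withr::local_tempdir()
  p <- file.path(dir, c("src.txt", "tgt.txt", "meta.jsonl"))
  write_parallel(ds, p[1], p[2], p[3])
  back <- read_parallel(p[1], p[2], p[3])
  expect_identical(as.data.frame(ds), as.data.frame(back))
  # empty dataset round-trips
  empty <- compile_strategy2(list(), lex, tb)
  write_parallel(empty, p[1], p[2], p[3])
  expect_equal(nrow(read_parallel(p[1], p[2], p[3])), 0L)
  # truncated target file
  write_parallel(ds, p[1], p[2], p[3])
  writeLines(readLines(p[2])[-1], p[2])
  expect_error(read_parallel(p[1], p[2]), "line counts differ")
})

test_that("strategy 2 spreads errors across the six types", {
  corpus <- generate_corpus(600, seed = 41, tables = tb)
  lex <- synthetic_lexicon(corpus, tb)
  ds <- compile_strategy2(corpus, lex, tb, seed = 42)
  shares <- table(factor(ds$error_type, levels = ERROR_TYPES))
  # every type fires, and no type exceeds half the dataset: the shuffled
  # group order balances types up to rule applicability
  expect_true(all(shares > 0))
  expect_lt(max(shares) / nrow(ds), 0.5)
})
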