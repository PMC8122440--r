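tb <- load_conjugations()

test_that("each rule group reproduces its worked transformation", {
  lex <- worked_examples_lexicon()
  expect_equal(apply_genre("unido", lex), "unida")
  expect_equal(apply_genre("traicioneras", lex), "traicioneros")
  expect_null(apply_genre("azul", lex))

  expect_equal(apply_number("aeronave", lex), "aeronaves")
  expect_equal(apply_number("virtudes", lex), "virtud")
  expect_null(apply_number("según", lex))  # candidate unattested

  expect_equal(apply_genre_number("sinuosos", lex), "sinuosa")
  expect_equal(apply_genre_number("abandonado", lex), "abandonadas")
  expect_null(apply_genre_number("azul", lex))

  expect_equal(apply_homophone("a", lex), "ha")
  expect_equal(apply_homophone("enebro", lex), "enhebro")
  expect_equal(apply_homophone("uso", lex), "huso")
  expect_null(apply_homophone("dato", lex))

  expect_equal(apply_suggestion("calle", lex, tb), "callé")
  expect_equal(apply_suggestion("agravio", lex, tb), "agrado")
  expect_equal(apply_suggestion("masa", lex, tb), "amas")

  set.seed(5)
  expect_equal(apply_concordance("llevan", tb, lex), "llevas")
  expect_equal(apply_concordance("peleaba", tb, lex), "peleábamos")
  expect_null(apply_concordance("mesa", tb, lex))
})

test_that("suggestion-based errors exclude what the other groups produce", {
  # "calles" (number) and "callo"-like forms would be reachable by rules;
  # with them attested, the suggester must still skip them
  lex <- new_lexicon(c("calle", "calles", "callé"), c(9, 6, 2))
  expect_equal(apply_suggestion("calle", lex, tb), "callé")
})

test_that("morphological and homophone rules invert their example pairs", {
  pairs <- list(c("unido", "unida"), c("traicioneras", "traicioneros"),
                c("aeronave", "aeronaves"), c("virtudes", "virtud"))
  for (p in pairs) {
    lex <- new_lexicon(p, 1)
    fwd <- if (is.null(apply_genre(p[1], lex))) apply_number(p[1], lex) else
      apply_genre(p[1], lex)
    bwd <- if (is.null(apply_genre(p[2], lex))) apply_number(p[2], lex) else
      apply_genre(p[2], lex)
    expect_equal(fwd, p[2])
    expect_equal(bwd, p[1])
  }
  hp <- list(c("a", "ha"), c("enebro", "enhebro"), c("uso", "huso"),
             c("tubo", "tuvo"), c("haya", "halla"))
  for (p in hp) {
    lex <- new_lexicon(p, 1)
    expect_equal(apply_homophone(p[1], lex), p[2])
    expect_equal(apply_homophone(p[2], lex), p[1])
  }
})

test_that("generate_error plants the first eligible match and skips the skip list", {
  lex <- new_lexicon(c("casos", "controles", "caso", "control", "el"), 1)
  sent <- c("El", "caso", "y", "el", "control", ".")
  rec <- generate_error(sent, "number", lex, tb, skip_list = c("el", "y"))
  # two eligible tokens; the earlier one takes the error
  expect_equal(rec$token_index, 2L)
  expect_equal(rec$error, "casos")
  expect_equal(rec$source, c("El", "casos", "y", "el", "control", "."))
  expect_equal(rec$target, sent)
  expect_equal(rec$distance, 1L)
  # skip-list-only sentence yields nothing
  expect_null(generate_error(c("El", "y", "el", "."), "number", lex, tb,
                             skip_list = c("el", "y")))
  # punctuation and the number mask are never error sites
  expect_null(generate_error(c("NUM", ".", ","), "number", lex, tb))
})

test_that("a capitalized first letter survives replacement", {
  lex <- new_lexicon(c("paciente", "pacientes"), 1)
  rec <- generate_error(c("Paciente", "estable", "."), "number", lex, tb,
                        skip_list = character())
  expect_equal(rec$error, "Pacientes")
  expect_equal(rec$original, "Paciente")
})

test_that("emitted records satisfy the type invariants on a synthetic corpus", {
  corpus <- generate_corpus(150, seed = 914, tables = tb)
  lex <- synthetic_lexicon(corpus, tb)
  set.seed(77)
  n_rec <- 0
  for (tokens in corpus) {
    for (type in ERROR_TYPES) {
      rec <- generate_error(tokens, type, lex, tb)
      if (is.null(rec)) next
      n_rec <- n_rec + 1
      diff <- which(rec$source != rec$target)
      expect_equal(diff, rec$token_index)
      expect_false(rec$error == rec$original)
      expect_true(lex_contains(lex, rec$error) ||
                    lex_contains(lex, tolower(rec$error)))
      expect_lte(rec$distance, DISTANCE_CAPS[[type]])
      expect_equal(rec$distance,
                   indel_distance(rec$original, rec$error))
    }
  }
  expect_gt(n_rec, 300)  # the groups fire broadly on the synthetic corpus
})

test_that("generate_error is deterministic given sentence, group and seed", {
  corpus <- generate_corpus(20, seed = 2, tables = tb)
  lex <- synthetic_lexicon(corpus, tb)
  for (type in c("number", "concordance", "suggestion")) {
    set.seed(123)
    a <- lapply(corpus, generate_error, type, lex, tb)
    set.seed(123)
    b <- lapply(corpus, generate_error, type, lex, tb)
    expect_identical(a, b)
  }
})
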