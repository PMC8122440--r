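#' Synthetic clinical-Spanish corpus generation
#'
#' A self-contained generator of short clinical-register Spanish sentences
#' whose vocabulary carries full genre/number paradigms, regular verb
#' conjugations and homophone variants, so that every error rule group can
#' fire and pass the real-word gate without any external corpus. Sentences
#' are emitted already normalized (words, the number mask and sentence
#' punctuation only).
#'
#' @name synthdata
NULL

.mini_lexicon <- function() .read_config("mini_lexicon.yml")
.templates <- function() unlist(.read_config("templates.yml")$templates)

.verb_paradigm <- function(infinitive, class, tables) {
  stem <- substr(infinitive, 1L, nchar(infinitive) - 2L)
  tt <- tables$terminations
  finite <- paste0(stem, tt$termination[tt$class == class])
  part <- if (class == "ar") "ad" else "id"
  participles <- paste0(stem, part, c("o", "a", "os", "as"))
  unique(c(infinitive, finite, participles))
}

#' All word forms of the synthetic mini-lexicon
#'
#' Expands the packaged mini-lexicon into its full closure: every genre,
#' number and genre-number paradigm member, the complete regular conjugation
#' (plus participles) of each verb, all *haber* forms, homophone pair
#' members and function words.
#'
#' @param tables A `conjugation_tables`.
#' @return Character vector of unique word forms.
#' @export
mini_lexicon_forms <- function(tables = load_conjugations()) {
  ml <- .mini_lexicon()
  forms <- c(
    unlist(ml$nouns4),
    unlist(lapply(ml$nouns, function(x) x[1:2])),
    unlist(ml$adjectives),
    unlist(ml$invariant_adjectives),
    unlist(lapply(ml$verbs, function(v) {
      .verb_paradigm(v[[1]], v[[2]], tables)
    })),
    tables$haber$form,
    unlist(ml$homophones),
    unlist(ml$function_words)
  )
  unique(enc2utf8(forms))
}

#' Lexicon over the synthetic vocabulary
#'
#' Builds a `lexicon` containing every mini-lexicon form (count 1), plus the
#' observed counts of a generated corpus when one is supplied. Including the
#' full closure guarantees that rule outputs on synthetic sentences are
#' attested regardless of which forms the corpus happened to sample.
#'
#' @param corpus Optional list of token vectors whose counts are added.
#' @param tables A `conjugation_tables`.
#' @return A `lexicon`.
#' @export
synthetic_lexicon <- function(corpus = NULL, tables = load_conjugations()) {
  forms <- mini_lexicon_forms(tables)
  counts <- rep(1L, length(forms))
  if (!is.null(corpus) && length(corpus)) {
    obs <- build_lexicon(corpus, min_count = 1L)
    extra <- setdiff(obs$words, forms)
    counts <- counts + lex_count(obs, forms)
    forms <- c(forms, extra)
    counts <- c(counts, lex_count(obs, extra))
  }
  new_lexicon(forms, counts)
}

.pick <- function(x) if (length(x) == 1L) x[[1]] else x[[sample.int(length(x), 1L)]]

.noun_pool <- function(ml) {
  c(lapply(ml$nouns4, function(x) list(forms = x, gender = NA)),
    lapply(ml$nouns, function(x) list(forms = x[1:2], gender = x[[3]])))
}

.det_form <- function(gender, number, definite) {
  tab <- if (definite) c(m_sg = "el", f_sg = "la", m_pl = "los", f_pl = "las")
         else c(m_sg = "un", f_sg = "una", m_pl = "unos", f_pl = "unas")
  tab[[paste(gender, number, sep = "_")]]
}

.finite_verb <- function(class, stem, number, tables) {
  mood <- .pick(c("indicative", "indicative", "indicative", "indicative",
                  "subjunctive"))
  tense <- .pick(c("present", "present", "present", "past", "past",
                   "future"))
  person <- if (number == "sg") 3L else 6L
  tt <- tables$terminations
  term <- tt$termination[tt$class == class & tt$mood == mood &
                           tt$tense == tense & tt$person == person]
  paste0(stem, term)
}

.new_group <- function(ml) {
  noun <- .pick(.noun_pool(ml))
  gender <- if (is.na(noun$gender)) .pick(c("m", "f")) else noun$gender
  number <- .pick(c("sg", "sg", "sg", "pl", "pl"))
  noun_form <- if (length(noun$forms) == 4L) {
    noun$forms[[match(paste(gender, number, sep = "_"),
                      c("m_sg", "f_sg", "m_pl", "f_pl"))]]
  } else {
    noun$forms[[if (number == "sg") 1L else 2L]]
  }
  list(gender = gender, number = number, noun = noun_form)
}

.fill_template <- function(template, ml, tables, number_mask) {
  slots <- strsplit(template, " ", fixed = TRUE)[[1]]
  groups <- list()
  get_group <- function(g) {
    if (is.null(groups[[g]])) groups[[g]] <<- .new_group(ml)
    groups[[g]]
  }
  hom_pool <- c("uso", "huso", "tubo", "vaso", "hecho")
  toks <- vapply(slots, function(s) {
    if (!grepl(":", s, fixed = TRUE)) {
      if (s == "num") return(number_mask)
      if (s == "hom") return(.pick(hom_pool))
      if (s == "part") {
        v <- .pick(ml$verbs)
        stem <- substr(v[[1]], 1L, nchar(v[[1]]) - 2L)
        return(paste0(stem, if (v[[2]] == "ar") "ado" else "ido"))
      }
      return(s)
    }
    kv <- strsplit(s, ":", fixed = TRUE)[[1]]
    grp <- get_group(kv[[2]])
    switch(kv[[1]],
      det = .det_form(grp$gender, grp$number, .pick(c(TRUE, TRUE, FALSE))),
      noun = grp$noun,
      adj = {
        a <- .pick(ml$adjectives)
        a[[match(paste(grp$gender, grp$number, sep = "_"),
                 c("m_sg", "f_sg", "m_pl", "f_pl"))]]
      },
      inv = .pick(ml$invariant_adjectives)[[
        if (grp$number == "sg") 1L else 2L]],
      verb = {
        v <- .pick(ml$verbs)
        .finite_verb(v[[2]], substr(v[[1]], 1L, nchar(v[[1]]) - 2L),
                     grp$number, tables)
      },
      haber = {
        tense <- .pick(c("present", "present", "past"))
        hb <- tables$haber
        hb$form[hb$mood == "indicative" & hb$tense == tense &
                  hb$person == (if (grp$number == "sg") 3L else 6L)]
      },
      stop("unknown slot kind: ", kv[[1]]))
  }, character(1), USE.NAMES = FALSE)
  toks[[1]] <- paste0(toupper(substr(toks[[1]], 1L, 1L)),
                      substr(toks[[1]], 2L, nchar(toks[[1]])))
  toks
}

#' Generate a synthetic clinical-Spanish corpus
#'
#' Draws `n` sentences from the packaged templates and mini-lexicon.
#' Sentences are 7 to 12 tokens long, already normalized, deterministic
#' under a fixed seed. With a few hundred sentences or more, every rule
#' group fires on at least one sentence (the packaged paradigms are closed
#' under the rules, so candidates pass the real-word gate).
#'
#' @param n Number of sentences.
#' @param seed Optional integer seed.
#' @param tables A `conjugation_tables`.
#' @param number_mask Mask token emitted for numeric slots.
#' @return List of `n` token vectors.
#' @export
generate_corpus <- function(n, seed = NULL, tables = load_conjugations(),
                            number_mask = NUMBER_MASK) {
  stopifnot(n >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(list())
  ml <- .mini_lexicon()
  templates <- .templates()
  lapply(seq_len(n), function(i) {
    .fill_template(.pick(templates), ml, tables, number_mask)
  })
}

#' Reference correctors
#'
#' Test harnesses for the evaluation pipeline: the oracle corrector returns
#' every record's target sentence (perfect correction), the identity
#' corrector returns the source unchanged (no correction).
#'
#' @param ds A `parallel_dataset`.
#' @return Character vector of corrected sentences, aligned with `ds`.
#' @export
oracle_corrector <- function(ds) ds$target

#' @rdname oracle_corrector
#' @export
identity_corrector <- function(ds) ds$source

.bigram_env <- function(corpus) {
  env <- new.env(parent = emptyenv())
  for (toks in corpus) {
    path <- c("<s>", toks, "</s>")
    keys <- paste(path[-length(path)], path[-1])
    for (k in keys) {
      env[[k]] <- (if (is.null(env[[k]])) 0L else env[[k]]) + 1L
    }
  }
  env
}

#' Context-frequency baseline corrector
#'
#' A simple real-word correction baseline: for each token, the candidate set
#' is the token itself plus every rule-group output attested in the lexicon
#' (the rules are largely involutive, so the correction of a planted error
#' is usually in the set). A candidate replaces the token only when its
#' summed left + right bigram count in the training corpus strictly exceeds
#' the token's own; ties conservatively keep the token. Deterministic.
#'
#' @param ds A `parallel_dataset` whose sources are to be corrected.
#' @param train_corpus List of token vectors providing bigram counts.
#' @param lex A `lexicon`.
#' @param tables A `conjugation_tables`.
#' @param number_mask Mask token (never edited).
#' @return Character vector of corrected sentences, aligned with `ds`.
#' @export
frequency_corrector <- function(ds, train_corpus, lex,
                                tables = load_conjugations(),
                                number_mask = NUMBER_MASK) {
  env <- .bigram_env(train_corpus)
  big <- function(a, b) {
    v <- env[[paste(a, b)]]
    if (is.null(v)) 0L else v
  }
  cand_types <- c("genre", "number", "genre_number", "homophone",
                  "concordance")
  vapply(sentence_tokens(ds$source), function(toks) {
    path <- c("<s>", toks, "</s>")
    out <- toks
    for (i in seq_along(toks)) {
      tok <- toks[[i]]
      if (.is_punct_token(tok) || tok == number_mask) next
      lower <- tolower(tok)
      cands <- unique(unlist(lapply(cand_types, function(tp) {
        .group_candidates(lower, tp, tables, lex)
      }), use.names = FALSE))
      cands <- cands[lex_contains(lex, cands)]
      if (length(cands) == 0) next
      prev <- path[[i]]
      nxt <- path[[i + 2L]]
      s0 <- big(prev, tok) + big(tok, nxt)
      scores <- vapply(cands, function(w) big(prev, w) + big(w, nxt),
                       integer(1))
      best <- which.max(scores)  # first of the ties in candidate order
      if (scores[best] > s0) {
        out[[i]] <- .recase_like(cands[[best]], tok)
      }
    }
    paste(out, collapse = " ")
  }, character(1))
}

#' Export and import the line-parallel dialect of translation toolkits
#'
#' `nmt_adapter_export()` writes the source and target sentence files a
#' sequence-to-sequence toolkit trains on; `nmt_adapter_import()` reads a
#' predictions file back and validates that it is line-aligned with the
#' expected number of source sentences.
#'
#' @param ds A `parallel_dataset`.
#' @param source_path,target_path Output sentence files.
#' @param path Predictions file, one sentence per line.
#' @param n_expected Expected number of lines.
#' @return `nmt_adapter_import()` returns a list of token vectors.
#' @export
nmt_adapter_export <- function(ds, source_path, target_path) {
  write_parallel(ds, source_path, target_path, meta_path = NULL)
}

#' @rdname nmt_adapter_export
#' @export
nmt_adapter_import <- function(path, n_expected) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) != n_expected) {
    stop("predictions file has ", length(lines), " lines, expected ",
         n_expected)
  }
  sentence_tokens(lines)
}
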