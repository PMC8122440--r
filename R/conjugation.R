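#' Load regular-verb conjugation tables
#'
#' Reads the packaged (or a user-supplied) YAML file listing the person
#' terminations of regular `-ar`/`-er`/`-ir` verbs for present, past
#' (imperfect) and future tense in indicative and subjunctive mood, plus the
#' full conjugation of the auxiliary *haber*. Only regular paradigms are
#' modelled.
#'
#' @param path Path to a YAML file; defaults to the packaged tables.
#' @return An object of class `conjugation_tables` with components
#'   `terminations` (a data frame with columns `termination`, `class`,
#'   `mood`, `tense`, `person`, ordered longest-termination-first) and
#'   `haber` (same layout with a `form` column).
#' @export
load_conjugations <- function(path = NULL) {
  cfg <- if (is.null(path)) .read_config("conjugations.yml") else
    yaml::read_yaml(path)
  rows <- list()
  for (cl in names(cfg$classes)) {
    for (mood in names(cfg$classes[[cl]])) {
      for (tense in names(cfg$classes[[cl]][[mood]])) {
        term <- enc2utf8(unlist(cfg$classes[[cl]][[mood]][[tense]]))
        stopifnot(length(term) == 6L)
        rows[[length(rows) + 1L]] <- data.frame(
          termination = term, class = cl, mood = mood, tense = tense,
          person = 1:6, stringsAsFactors = FALSE)
      }
    }
  }
  terminations <- do.call(rbind, rows)
  # fixed resolution order: longer terminations first, then class ar/er/ir,
  # indicative before subjunctive, present/past/future, person
  class_rank <- match(terminations$class, c("ar", "er", "ir"))
  mood_rank <- match(terminations$mood, c("indicative", "subjunctive"))
  tense_rank <- match(terminations$tense, c("present", "past", "future"))
  terminations <- terminations[order(-nchar(terminations$termination),
                                     class_rank, mood_rank, tense_rank,
                                     terminations$person), ]
  rownames(terminations) <- NULL

  hrows <- list()
  for (mood in names(cfg$haber)) {
    for (tense in names(cfg$haber[[mood]])) {
      forms <- enc2utf8(unlist(cfg$haber[[mood]][[tense]]))
      stopifnot(length(forms) == 6L)
      hrows[[length(hrows) + 1L]] <- data.frame(
        form = forms, mood = mood, tense = tense, person = 1:6,
        stringsAsFactors = FALSE)
    }
  }
  haber <- do.call(rbind, hrows)
  structure(list(terminations = terminations, haber = haber),
            class = "conjugation_tables")
}

#' @export
print.conjugation_tables <- function(x, ...) {
  cat("<conjugation_tables>", nrow(x$terminations), "terminations,",
      nrow(x$haber), "haber forms\n")
  invisible(x)
}

#' Identify a regular conjugated verb form
#'
#' Matches the word's ending against the listed person terminations, longest
#' termination first; a match is accepted when the reconstructed infinitive
#' (stem + class ending) is attested in the lexicon. If no termination
#' yields an attested infinitive, the whole word is compared against the
#' conjugation of *haber*. The input is lower-cased before matching.
#'
#' @param word Word to analyse.
#' @param tables A `conjugation_tables` object.
#' @param lex A `lexicon` used to attest reconstructed infinitives.
#' @return A list with fields `word`, `stem`, `termination`, `infinitive`,
#'   `class`, `mood`, `tense`, `person`, `is_haber`; or `NULL` if the word is
#'   not identified as a regular verb form.
#' @export
identify_verb <- function(word, tables, lex) {
  stopifnot(nzchar(word))
  w <- tolower(enc2utf8(word))
  tt <- tables$terminations
  hit <- endsWith(w, tt$termination) & nchar(w) > nchar(tt$termination)
  for (i in which(hit)) {
    stem <- substr(w, 1L, nchar(w) - nchar(tt$termination[i]))
    inf <- paste0(stem, tt$class[i])
    if (lex_contains(lex, inf)) {
      return(list(word = w, stem = stem, termination = tt$termination[i],
                  infinitive = inf, class = tt$class[i], mood = tt$mood[i],
                  tense = tt$tense[i], person = tt$person[i],
                  is_haber = FALSE))
    }
  }
  j <- match(w, tables$haber$form)
  if (!is.na(j)) {
    hb <- tables$haber[j, ]
    return(list(word = w, stem = "", termination = w, infinitive = "haber",
                class = "haber", mood = hb$mood, tense = hb$tense,
                person = hb$person, is_haber = TRUE))
  }
  NULL
}

# all person-swap forms for a verb analysis, excluding the original word
.concordance_forms <- function(analysis, tables) {
  if (analysis$is_haber) {
    hb <- tables$haber
    forms <- hb$form[hb$mood == analysis$mood & hb$tense == analysis$tense]
  } else {
    tt <- tables$terminations
    sel <- tt$class == analysis$class & tt$mood == analysis$mood &
      tt$tense == analysis$tense
    forms <- paste0(analysis$stem, tt$termination[sel])
  }
  unique(forms[forms != analysis$word])
}

#' Generate a subject-verb concordance error
#'
#' If `word` is identified as a regular conjugated form (or a form of
#' *haber*), its person is changed to a randomly drawn different person of
#' the same tense and mood (same conjugation class; *haber* forms swap within
#' their own paradigm). Candidate persons are tried in random order and the
#' first one producing a form that is attested in the lexicon, differs from
#' the input and lies within `distance_cap` insert/delete edit operations is
#' returned.
#'
#' @inheritParams identify_verb
#' @param distance_cap Maximum insert/delete distance of the error to the
#'   original word (6 covers every person swap in the packaged paradigms).
#' @return The erroneous form, or `NULL` when the word is not a verb or no
#'   admissible person swap exists.
#' @export
apply_concordance <- function(word, tables, lex, distance_cap = 6L) {
  analysis <- identify_verb(word, tables, lex)
  if (is.null(analysis)) return(NULL)
  forms <- .concordance_forms(analysis, tables)
  if (length(forms) == 0) return(NULL)
  if (length(forms) > 1) forms <- sample(forms)
  for (f in forms) {
    if (lex_contains(lex, f) &&
        indel_distance(analysis$word, f) <= distance_cap) {
      return(f)
    }
  }
  NULL
}
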