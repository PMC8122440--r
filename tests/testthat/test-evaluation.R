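tb <- load_conjugations()

test_that("metric formulas reproduce reported operating points", {
  # printed (R, P, F0.5) rows recompute within the rounding of their inputs
  cells <- list(c(50.92, 69.79, 64.98),
                c(78.41, 93.34, 89.92),
                c(48.10, 84.83, 73.59))
  for (cell in cells) {
    expect_equal(f05_score(cell[1], cell[2]), cell[3], tolerance = 0.05 / cell[3])
  }
  # algebraic identity: R = P = x implies F0.5 = x
  for (x in c(1, 37.5, 80, 100)) expect_equal(f05_score(x, x), x)
  # 0/0 convention
  expect_equal(unname(compute_metrics(0, 0, 0)), c(0, 0, 0))
  expect_equal(unname(compute_metrics(10, 0, 0)), c(0, 0, 0))
})

test_that("compute_metrics scales counts to percentages", {
  m <- compute_metrics(total_errors = 200, corrected = 100,
                       bad_corrections = 50)
  expect_equal(unname(m["recall"]), 50)
  expect_equal(unname(m["precision"]), 100 * 100 / 150)
  expect_true(m["f05"] > min(m[1:2]) && m["f05"] < max(m[1:2]))
})

test_that("classify_outcomes counts corrections and bad corrections", {
  ds <- structure(data.frame(
    id = 1:3, split = NA_character_,
    error_type = c("genre", "number", "identity"),
    token_index = c(2L, 1L, NA), original = c("unido", "caso", NA),
    error = c("unida", "casos", NA), distance = c(2L, 1L, NA),
    source = c("sangrado unida .", "casos estable .", "todo bien ."),
    target = c("sangrado unido .", "caso estable .", "todo bien ."),
    stringsAsFactors = FALSE), class = c("parallel_dataset", "data.frame"))
  # oracle output: everything corrected, nothing bad
  co <- classify_outcomes(ds, oracle_corrector(ds))
  ov <- co[co$error_type == "overall", ]
  expect_equal(ov$total_errors, 2)
  expect_equal(ov$corrected, 2)
  expect_equal(ov$bad_corrections, 0)
  # identity output: nothing corrected, nothing bad
  ci <- classify_outcomes(ds, identity_corrector(ds))
  expect_equal(ci[ci$error_type == "overall", ]$corrected, 0)
  expect_equal(ci[ci$error_type == "overall", ]$bad_corrections, 0)
  # changing a non-error token to a wrong word is one bad correction;
  # mangling an identity sentence too
  out <- c("sangrado unido .", "caso grave .", "nada bien .")
  cb <- classify_outcomes(ds, out)
  expect_equal(cb[cb$error_type == "overall", ]$corrected, 2)
  expect_equal(cb[cb$error_type == "overall", ]$bad_corrections, 2)
  expect_equal(cb[cb$error_type == "identity", ]$bad_corrections, 1)
  # misalignment is an error
  expect_error(classify_outcomes(ds, out[1:2]), "3 records")
})

test_that("evaluate_corrections aggregates per type plus overall", {
  corpus <- generate_corpus(200, seed = 51, tables = tb)
  lex <- synthetic_lexicon(corpus, tb)
  ds <- compile_strategy1(corpus, lex, tb, seed = 52)
  rep <- evaluate_corrections(ds, oracle_corrector(ds))
  expect_s3_class(rep, "eval_report")
  expect_equal(rep$error_type[nrow(rep)], "overall")
  expect_setequal(setdiff(rep$error_type, "overall"),
                  unique(ds$error_type))
  ov <- rep[rep$error_type == "overall", ]
  expect_equal(ov$recall, 100)
  expect_equal(ov$precision, 100)
  expect_equal(ov$f05, 100)
  # metrics invariant under record order
  perm <- sample(nrow(ds))
  rep2 <- evaluate_corrections(ds[perm, ], oracle_corrector(ds)[perm])
  expect_equal(rep2[match(rep$error_type, rep2$error_type), -1], rep[, -1],
               ignore_attr = TRUE)
  # empty input: no rows except a zeroed overall, no division errors
  rep0 <- evaluate_corrections(ds[0, ], character())
  expect_equal(rep0$recall, 0)
})

test_that("a half-oracle corrector scores recall 50 on a balanced fixture", {
  corpus <- generate_corpus(100, seed = 61, tables = tb)
  lex <- synthetic_lexicon(corpus, tb)
  ds <- compile_strategy2(corpus, lex, tb, seed = 62)
  ds <- ds[ds$error_type != "identity", ]
  n <- nrow(ds) - nrow(ds) %% 2
  ds <- ds[seq_len(n), ]
  out <- ifelse(seq_len(n) %% 2 == 0, oracle_corrector(ds),
                identity_corrector(ds))
  rep <- evaluate_corrections(ds, out)
  expect_equal(rep[rep$error_type == "overall", ]$recall, 50)
  expect_equal(rep[rep$error_type == "overall", ]$precision, 100)
})

test_that("reports serialize to TSV and JSON", {
  df <- evaluate_corrections(
    structure(data.frame(
      id = 1L, split = NA_character_, error_type = "genre",
      token_index = 2L, original = "unido", error = "unida",
      distance = 2L, source = "sangrado unida .",
      target = "sangrado unido .", stringsAsFactors = FALSE),
      class = c("parallel_dataset", "data.frame")),
    "sangrado unido .")
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "r.tsv")
  js <- file.path(dir, "r.json")
  write_report(df, tsv, "tsv")
  write_report(df, js, "json")
  back <- utils::read.delim(tsv)
  expect_equal(back$f05[back$error_type == "overall"], 100)
  expect_equal(jsonlite::fromJSON(js)$recall, c(100, 100))
})
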