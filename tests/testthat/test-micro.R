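lex <- load_lexicon()
kw <- load_keywords()

test_that("morpheme counts follow the tag-plus-stem rule", {
  t <- tr("C: he jump/ed .", "C: he's run/ing .", "C: dog/s and cat/s .")
  expect_equal(count_morphemes(t, 1), 3)
  expect_equal(count_morphemes(t, 2), 4)
  expect_equal(count_morphemes(t, 3), 5)
  # maze tokens contribute nothing
  t2 <- tr("C: (um the) he jump/ed .")
  expect_equal(count_morphemes(t2, 1), 3)
  # unintelligible stretches contribute their configured word mass
  t3 <- tr("C: he saw XX .")
  expect_equal(count_morphemes(t3, 1), 4)
  expect_equal(count_morphemes(t3, 1, xx_words = 3), 5)
})

test_that("length and rate metrics match hand counts", {
  t <- tr("C: the boy found a map .", "C: he ran .", duration = 60)
  r <- compute_micro_report(t, lex, kw)
  expect_equal(r$mlu_words_full, 3.5)
  expect_equal(r$max_words_full, 5)
  expect_equal(r$total_utterances, 2)
  expect_equal(r$total_words, 7)
  expect_equal(r$words_per_minute, 7)

  # 120 words over 60 s gives 120 words per minute
  g <- gen_transcript(seed = 2, age_months = 60, target_words = 120,
                      maze_rate = 0, unintelligible_rate = 0,
                      secondary_mean = 0, duration_missing_rate = 0)
  t2 <- g$transcript
  t2$duration_s <- 60
  r2 <- compute_micro_report(t2, lex, kw)
  expect_equal(r2$words_per_minute, 120)
})

test_that("type-token ratio is computed over non-maze intelligible tokens", {
  t <- tr("C: the boy the map .")
  expect_equal(compute_micro_report(t, lex, kw)$ttr, 0.75)
  # maze content does not enter the type count
  t2 <- tr("C: (um um) the boy the map .")
  expect_equal(compute_micro_report(t2, lex, kw)$ttr, 0.75)
})

test_that("intelligibility uses word mass over child non-maze tokens", {
  t <- tr("C: the boy found a map near the door .",
          "C: he saw a X .")
  r <- compute_micro_report(t, lex, kw)
  expect_equal(r$unintelligible_words, 1)
  # 11 intelligible + 1 unintelligible words
  expect_equal(r$intelligibility_pct, 100 * 11 / 12)

  t2 <- tr("C: he saw one two three four five six seven X .")
  r2 <- compute_micro_report(t2, lex, kw)
  expect_equal(r2$intelligibility_pct, 90)
})

test_that("keywords and synonyms count lemma matches outside mazes", {
  t <- tr("C: he saw the map .", "C: the map was old .",
          "C: she found the gold .", "C: (the treasure) he ran .")
  k <- count_keywords(t, kw)
  expect_equal(unname(k["keywords"]), 2)
  expect_equal(unname(k["synonyms"]), 1)
  # secondary speaker keywords do not count
  t2 <- tr("P: where is the map ?")
  expect_equal(unname(count_keywords(t2, kw)["keywords"]), 0)
  # empty config
  empty <- structure(list(keywords = character(), synonyms = list()),
                     class = "keyword_config")
  expect_equal(unname(count_keywords(t, empty)), c(0, 0))
})

test_that("bound and irregular morphology are counted separately", {
  t <- tr("C: he went home .", "C: they jump/ed and walk/ed .",
          "C: the men saw two dog/s .", "C: she climb/3s the boy/z hill .")
  b <- count_bound_morphology(t, lex)
  expect_equal(b$irregular_past, 2)  # went, saw
  expect_equal(b$regular_past_ed, 2)
  expect_equal(b$irregular_plurals, 1)
  expect_equal(b$regular_plurals, 1)
  expect_equal(b$third_person_regular, 1)
  expect_equal(b$possessive_z, 1)
})

test_that("degree forms require adjective stems or irregular maps", {
  t <- tr("C: the tree is bigger .", "C: the best day .",
          "C: the river is deep .", "C: the tallest tree .")
  d <- count_degree_forms(t, lex)
  expect_equal(unname(d["comparatives"]), 1)
  expect_equal(unname(d["superlatives"]), 2)
})

test_that("full-transcript and analysis-set metrics coincide on clean input", {
  g <- gen_transcript(seed = 9, age_months = 84, maze_rate = 0,
                      unintelligible_rate = 0, incomplete_rate = 0)
  r <- compute_micro_report(g$transcript, lex, kw)
  expect_equal(r$mlu_words_as, r$mlu_words_full)
  expect_equal(r$mlu_morphemes_as, r$mlu_morphemes_full)
  expect_equal(r$max_words_as, r$max_words_full)
  expect_equal(r$max_morphemes_as, r$max_morphemes_full)
})

test_that("copula and auxiliary counts partition the BE tokens", {
  for (s in 1:15) {
    g <- gen_transcript(seed = 200 + s, age_months = sample(48:95, 1))
    t <- tag_pos(g$transcript, lex)
    r <- compute_micro_report(t, lex, kw)
    be_n <- sum(t$tokens$pos %in% c("copula_c", "copula_u", "aux_c",
                                    "aux_u"), na.rm = TRUE)
    expect_equal(r$contractible_copula + r$uncontractible_copula +
                   r$contractible_auxiliary + r$uncontractible_auxiliary,
                 be_n)
  }
})

test_that("all 44 metrics equal an independent token-scan recount", {
  for (s in 1:60) {
    g <- gen_transcript(seed = 3000 + s, age_months = sample(48:95, 1))
    t <- tag_pos(g$transcript, lex)
    r <- compute_micro_report(t, lex, kw)
    o <- oracle_micro(t, lex, kw)
    for (m in names(o))
      expect_equal(r[[m]], o[[m]], info = sprintf("seed %d metric %s", s, m))
  }
})

test_that("total words ignore maze content while maze spans count it", {
  t <- tr("C: the boy found a map .")
  t2 <- tr("C: the boy (um uh) found a (the) map .")
  r <- compute_micro_report(t, lex, kw)
  r2 <- compute_micro_report(t2, lex, kw)
  expect_equal(r2$total_words, r$total_words)
  expect_equal(r$maze_count, 0)
  expect_equal(r2$maze_count, 2)
})

test_that("undefined metrics are NA, never zero", {
  t <- tr("P: tell me more .")
  r <- compute_micro_report(t, lex, kw)
  expect_equal(r$total_utterances, 0)
  expect_true(is.na(r$mlu_words_full))
  expect_true(is.na(r$ttr))
  expect_true(is.na(r$words_per_minute))
  # incomplete-only child speech: full metrics defined, analysis set empty
  t2 <- tr("C: he ran>")
  r2 <- compute_micro_report(t2, lex, kw)
  expect_false(is.na(r2$mlu_words_full))
  expect_true(is.na(r2$mlu_words_as))
})

test_that("report exports keep all 44 metrics with conventional labels", {
  g <- gen_transcript(seed = 21, age_months = 60)
  r <- compute_micro_report(g$transcript, lex, kw)
  df <- as.data.frame(r)
  expect_equal(ncol(df), 45)  # id + 44 metrics
  p <- tempfile(fileext = ".csv")
  write_micro_csv(list(r), p)
  hdr <- names(utils::read.csv(p, check.names = FALSE))
  expect_true("Mean length of utterance (words) full transcript" %in% hdr)
  expect_length(hdr, 45)
  js <- jsonlite::fromJSON(micro_report_json(r))
  expect_equal(js$total_words, r$total_words)
  unlink(p)
})
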