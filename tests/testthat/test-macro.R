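rub <- load_rubric()

test_that("the default rubric loads with all seven elements", {
  expect_s3_class(rub, "rubric_matrix")
  expect_named(rub$elements,
               c("setting", "initiating_event", "internal_response", "plan",
                 "attempt", "consequence", "character"))
})

test_that("rubric schema violations are named", {
  raw <- yaml::read_yaml(system.file("extdata", "rubric.yaml",
                                     package = "storysampler"))
  p <- tempfile(fileext = ".yaml")

  bad <- raw; bad$elements$plan <- NULL
  yaml::write_yaml(bad, p)
  expect_error(load_rubric(p), "missing element.*plan")

  bad <- raw; bad$elements$setting$descriptors[["4"]] <- "too much"
  yaml::write_yaml(bad, p)
  expect_error(load_rubric(p), "levels 0-3")

  bad <- raw; bad$elements$attempt$core_cues <- list()
  yaml::write_yaml(bad, p)
  expect_error(load_rubric(p), "empty cue set")
  unlink(p)
})

test_that("element scores follow the cue thresholds", {
  # nothing matches -> 0 (unobserved)
  t0 <- tr("C: he walk/ed there .")
  expect_equal(score_element(t0, "setting", rub)$score, 0L)
  # elaboration cue only -> 1
  t1 <- tr("C: it was a sunny morning .")
  expect_equal(score_element(t1, "setting", rub)$score, 1L)
  # core cue only -> 2
  t2 <- tr("C: one day he walk/ed there .")
  expect_equal(score_element(t2, "setting", rub)$score, 2L)
  # core + elaboration -> 3
  t3 <- tr("C: one day he walk/ed there .", "C: it was a sunny morning .")
  r3 <- score_element(t3, "setting", rub)
  expect_equal(r3$score, 3L)
  expect_true(length(r3$matched) >= 2)
  # attempt core cue only -> 2
  t4 <- tr("C: he dug a hole .")
  expect_equal(score_element(t4, "attempt", rub)$score, 2L)
})

test_that("a higher elaboration threshold demands more distinct cues", {
  t <- tr("C: one day he walk/ed .", "C: it was a sunny morning .")
  expect_equal(score_element(t, "setting", rub, k_elaboration = 2)$score, 2L)
  t2 <- tr("C: one day he walk/ed .", "C: it was a sunny morning far away .")
  expect_equal(score_element(t2, "setting", rub, k_elaboration = 2)$score, 3L)
})

test_that("maze material and secondary speakers never score", {
  t <- tr("C: (one day) he walk/ed .")
  expect_equal(score_element(t, "setting", rub)$score, 0L)
  t2 <- tr("P: one day what happen/ed ?", "C: he walk/ed .")
  expect_equal(score_element(t2, "setting", rub)$score, 0L)
  expect_equal(score_element(t2, "setting", rub, include_other = TRUE)$score,
               2L)
})

test_that("composite equals the element sum and recovers planted levels", {
  levels <- c(setting = 2L, initiating_event = 3L, internal_response = 0L,
              plan = 1L, attempt = 2L, consequence = 3L, character = 3L)
  g <- gen_transcript(seed = 77, age_months = 72,
                      planted_macro_levels = levels)
  m <- score_macro(g$transcript, rub)
  expect_equal(m$element_scores, levels)
  expect_equal(m$composite, 14L)
  expect_equal(m$composite, sum(m$element_scores))
})

test_that("fully realized and empty narratives hit the scale ends", {
  g3 <- gen_transcript(seed = 5, age_months = 84,
                       planted_macro_levels = stats::setNames(
                         rep(3L, 7), names(load_rubric()$elements)))
  expect_equal(score_macro(g3$transcript, rub)$composite, 21L)
  t0 <- tr("C: he walk/ed there .")
  expect_equal(score_macro(t0, rub)$composite, 0L)
})

test_that("composite conservation holds across random transcripts", {
  for (s in 1:20) {
    g <- gen_transcript(seed = 400 + s, age_months = sample(48:95, 1))
    m <- score_macro(g$transcript, rub)
    expect_equal(m$composite, sum(m$element_scores))
    expect_true(all(m$element_scores >= 0 & m$element_scores <= 3))
  }
})

test_that("adding cue-matching content never lowers a score", {
  for (s in 1:10) {
    g <- gen_transcript(seed = 500 + s, age_months = 60)
    before <- score_macro(g$transcript, rub)$element_scores
    extra <- c("C: one day they went to the beach .",
               "C: he found a map .",
               "C: the boy was excited .")
    lines <- c(g$lines, extra)
    after <- score_macro(parse_transcript(lines), rub)$element_scores
    expect_true(all(after >= before))
  }
})

test_that("batch scoring keeps order and survives bad entries", {
  gs <- lapply(1:10, function(s)
    gen_transcript(seed = s, age_months = 60)$transcript)
  tab <- batch_score(gs, rub)
  expect_equal(nrow(tab), 10)
  expect_equal(tab$composite,
               vapply(gs, function(t) score_macro(t, rub)$composite, 0L))

  bad <- tempfile()
  writeLines("not a transcript", bad)
  paths <- c(vapply(gs[1:2], function(t) {
    p <- tempfile(fileext = ".txt"); write_transcript(t, p); p
  }, ""), bad)
  tab2 <- batch_score(paths, rub)
  expect_equal(nrow(tab2), 3)
  expect_true(is.na(tab2$composite[3]))
  expect_length(attr(tab2, "failures"), 1)
  unlink(c(paths, bad))

  expect_equal(nrow(batch_score(list())), 0)
})

test_that("planted levels are recovered at scale", {
  n <- 60; hits <- 0L; total <- 0L
  for (s in seq_len(n)) {
    levels <- stats::setNames(sample(0:3, 7, replace = TRUE),
                              names(rub$elements))
    g <- gen_transcript(seed = 6000 + s, age_months = sample(48:95, 1),
                        planted_macro_levels = levels)
    m <- score_macro(g$transcript, rub)
    hits <- hits + sum(m$element_scores == levels)
    total <- total + 7L
  }
  expect_gte(hits / total, 0.95)
})
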