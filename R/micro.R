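#' @title Micro-structure metrics
#'
#' @description
#' The 44 micro-structure metrics summarise a child's within-utterance
#' language: utterance length in words and morphemes (over the full
#' transcript and over the cleaned analysis set), productivity, lexical
#' diversity, story keywords, part-of-speech counts, bound and irregular
#' morphology, copula/auxiliary BE forms, intelligibility, mazes, degree
#' forms and speech rate. Maze tokens are excluded from every word,
#' morpheme and category count but are themselves counted as maze spans;
#' unintelligible stretches contribute configurable word mass.
#'
#' @name microstructure
NULL

MICRO_METRICS <- c(
  "mlu_words_full", "mlu_morphemes_full", "max_words_full",
  "max_morphemes_full", "mlu_words_as", "mlu_morphemes_as", "max_words_as",
  "max_morphemes_as", "total_utterances", "total_words", "keywords",
  "keyword_synonyms", "ttr", "nouns", "pronouns", "verbs",
  "relative_pronouns", "adverbs", "adjectives", "determiners", "particles",
  "prepositions", "present_progressives", "questions",
  "subordinate_conjunctions", "coordinating_conjunctions",
  "regular_plurals", "irregular_plurals", "possessive_z", "articles",
  "regular_past_ed", "irregular_past", "third_person_regular",
  "third_person_irregular", "unintelligible_words", "intelligibility_pct",
  "maze_count", "comparatives", "superlatives", "contractible_copula",
  "uncontractible_copula", "contractible_auxiliary",
  "uncontractible_auxiliary", "words_per_minute"
)

#' Count morphemes in one utterance
#'
#' Each non-maze token contributes one morpheme for its stem plus one per
#' bound-morpheme tag; a clitic is its own token and contributes one
#' (so `he's run/ing` counts four). An unintelligible stretch contributes
#' its configured word mass.
#'
#' @param t A `transcript`.
#' @param utt Utterance index within the transcript.
#' @param xx_words Word mass of an `XX` (multi-word unintelligible)
#'   stretch; a single `X` always counts 1.
#' @return Integer morpheme count.
#' @export
count_morphemes <- function(t, utt, xx_words = 2) {
  stopifnot(inherits(t, "transcript"))
  tk <- t$tokens[t$tokens$utt == utt & !t$tokens$maze, , drop = FALSE]
  sum(token_morpheme_weight(tk, xx_words))
}

token_morpheme_weight <- function(tk, xx_words = 2) {
  ntags <- ifelse(nzchar(tk$morph),
                  lengths(strsplit(tk$morph, ",", fixed = TRUE)), 0L)
  w <- 1 + ntags
  w[tk$unintelligible & tk$surface == "XX"] <- xx_words
  w
}

#' Compute the full micro-structure report
#'
#' Computes all 44 micro-structure metrics for one tagged transcript.
#' Full-transcript length metrics use every child utterance; analysis-set
#' metrics use [build_analysis_set()]. Metrics that are undefined (no child
#' utterances; no recorded duration for words per minute; empty analysis
#' set) are reported as `NA`, never as 0.
#'
#' @param t A `transcript`; tagged with [tag_pos()] first if `pos` is
#'   unfilled.
#' @param lex A `lexicon`; default bundled lexicon.
#' @param kw A `keyword_config`; default bundled example.
#' @param xx_words Word mass of an `XX` stretch (default 2).
#' @return A `micro_report`: named list of the 44 metrics.
#' @examples
#' t <- parse_transcript(c("@id: P1", "@age_months: 60",
#'                         "C: the boy found a map .",
#'                         "C: he jump/ed ."))
#' rep <- compute_micro_report(t)
#' rep$mlu_words_full
#' @export
compute_micro_report <- function(t, lex = load_lexicon(),
                                 kw = load_keywords(), xx_words = 2) {
  stopifnot(inherits(t, "transcript"))
  if (all(is.na(t$tokens$pos))) t <- tag_pos(t, lex)
  tk <- t$tokens
  child <- child_token_mask(t)
  nm <- !tk$maze
  int <- !tk$unintelligible
  lemma <- tolower(token_lemma(t))
  ww <- token_word_weight(t, xx_words)
  mw <- token_morpheme_weight(tk, xx_words)

  child_utts <- t$utterances$index[t$utterances$speaker == "C"]
  r <- stats::setNames(as.list(rep(NA_real_, length(MICRO_METRICS))),
                       MICRO_METRICS)

  r$total_utterances <- length(child_utts)
  if (length(child_utts)) {
    len <- utterance_lengths(tk, child_utts, ww, mw)
    r$mlu_words_full <- mean(len$words)
    r$mlu_morphemes_full <- mean(len$morphemes)
    r$max_words_full <- max(len$words)
    r$max_morphemes_full <- max(len$morphemes)
  }

  as_t <- build_analysis_set(t)
  if (nrow(as_t$utterances)) {
    aww <- token_word_weight(as_t, xx_words)
    amw <- token_morpheme_weight(as_t$tokens, xx_words)
    alen <- utterance_lengths(as_t$tokens, as_t$utterances$index, aww, amw)
    r$mlu_words_as <- mean(alen$words)
    r$mlu_morphemes_as <- mean(alen$morphemes)
    r$max_words_as <- max(alen$words)
    r$max_morphemes_as <- max(alen$morphemes)
  }

  r$total_words <- sum(ww[child & nm])
  kwc <- count_keywords(t, kw)
  r$keywords <- kwc[["keywords"]]
  r$keyword_synonyms <- kwc[["synonyms"]]

  tok_ok <- child & nm & int
  if (any(tok_ok))
    r$ttr <- length(unique(lemma[tok_ok])) / sum(tok_ok)

  pos_counts <- table(tk$pos[tok_ok])
  pc <- function(lbl) sum(pos_counts[names(pos_counts) %in% lbl])
  r$nouns <- pc("noun"); r$pronouns <- pc("pronoun")
  r$verbs <- pc("verb"); r$relative_pronouns <- pc("rel_pronoun")
  r$adverbs <- pc("adverb"); r$adjectives <- pc("adjective")
  r$determiners <- pc("determiner"); r$particles <- pc("particle")
  r$prepositions <- pc("preposition"); r$articles <- pc("article")
  r$subordinate_conjunctions <- pc("conj_sub")
  r$coordinating_conjunctions <- pc("conj_coord")
  r$contractible_copula <- pc("copula_c")
  r$uncontractible_copula <- pc("copula_u")
  r$contractible_auxiliary <- pc("aux_c")
  r$uncontractible_auxiliary <- pc("aux_u")

  bm <- count_bound_morphology(t, lex)
  for (nm2 in names(bm)) r[[nm2]] <- bm[[nm2]]

  deg <- count_degree_forms(t, lex)
  r$comparatives <- deg[["comparatives"]]
  r$superlatives <- deg[["superlatives"]]

  r$questions <- sum(t$utterances$speaker == "C" &
                       t$utterances$terminator == "?")

  unint_w <- sum(ww[child & nm & !int])
  int_w <- sum(ww[child & nm & int])
  r$unintelligible_words <- unint_w
  if (int_w + unint_w > 0)
    r$intelligibility_pct <- 100 * (1 - unint_w / (int_w + unint_w))

  r$maze_count <- count_maze_spans(tk, child_utts)

  if (!is.na(t$duration_s))
    r$words_per_minute <- r$total_words / (t$duration_s / 60)

  structure(r, class = "micro_report", id = t$id,
            n_analysis_set = nrow(as_t$utterances))
}

utterance_lengths <- function(tk, utts, ww, mw) {
  keep <- !tk$maze
  words <- vapply(utts, function(u) sum(ww[keep & tk$utt == u]), 0)
  morphemes <- vapply(utts, function(u) sum(mw[keep & tk$utt == u]), 0)
  list(words = words, morphemes = morphemes)
}

count_maze_spans <- function(tk, utts) {
  n <- 0L
  for (u in utts) {
    m <- tk$maze[tk$utt == u]
    if (length(m)) {
      r <- rle(m)
      n <- n + sum(r$values)
    }
  }
  n
}

#' Count story keywords and their synonyms
#'
#' Counts child token lemmas (mispronunciation targets and tag-stripped
#' bases) matching the keyword set and, separately, any synonym set. Maze
#' and secondary-speaker tokens are excluded.
#'
#' @inheritParams compute_micro_report
#' @return Named numeric vector `c(keywords = , synonyms = )`.
#' @export
count_keywords <- function(t, kw = load_keywords()) {
  stopifnot(inherits(t, "transcript"), inherits(kw, "keyword_config"))
  tk <- t$tokens
  ok <- child_token_mask(t) & !tk$maze & !tk$unintelligible
  lemma <- tolower(token_lemma(t))[ok]
  c(keywords = sum(lemma %in% kw$keywords),
    synonyms = sum(lemma %in% unlist(kw$synonyms)))
}

#' Count bound and irregular morphology
#'
#' Regular morphology comes from the transcriber's morpheme tags; irregular
#' plurals, pasts and third-person forms are recognised from the lexicon's
#' irregular sets on untagged tokens. Maze tokens are excluded.
#'
#' @inheritParams compute_micro_report
#' @return Named list: `regular_plurals`, `irregular_plurals`,
#'   `possessive_z`, `regular_past_ed`, `irregular_past`,
#'   `third_person_regular`, `third_person_irregular`,
#'   `present_progressives`.
#' @export
count_bound_morphology <- function(t, lex = load_lexicon()) {
  stopifnot(inherits(t, "transcript"))
  tk <- t$tokens
  ok <- child_token_mask(t) & !tk$maze & !tk$unintelligible
  tags <- strsplit(tk$morph, ",", fixed = TRUE)
  has_tag <- function(tag) vapply(tags, function(x) tag %in% x, TRUE)
  lemma <- tolower(token_lemma(t))
  untagged <- !nzchar(tk$morph)
  list(
    regular_plurals = sum(ok & has_tag("s")),
    irregular_plurals = sum(ok & untagged & lemma %in% lex$irregular_plurals),
    possessive_z = sum(ok & has_tag("z")),
    regular_past_ed = sum(ok & has_tag("ed")),
    irregular_past = sum(ok & untagged & lemma %in% lex$irregular_pasts),
    third_person_regular = sum(ok & has_tag("3s")),
    third_person_irregular = sum(ok & untagged & lemma %in% lex$irregular_3rd),
    present_progressives = sum(ok & has_tag("ing"))
  )
}

#' Count comparative and superlative forms
#'
#' Matches `-er`/`-est` suffixed forms whose stem is a lexicon adjective
#' (so `river` never counts) plus the irregular degree maps
#' (`better`/`best`, `more`/`most`, `worse`/`worst`).
#'
#' @inheritParams compute_micro_report
#' @return Named numeric vector `c(comparatives = , superlatives = )`.
#' @export
count_degree_forms <- function(t, lex = load_lexicon()) {
  stopifnot(inherits(t, "transcript"))
  tk <- t$tokens
  ok <- child_token_mask(t) & !tk$maze & !tk$unintelligible & !tk$clitic &
    !nzchar(tk$morph)
  lemma <- tolower(token_lemma(t))
  deg <- vapply(lemma[ok], detect_degree, "", lex = lex,
                USE.NAMES = FALSE)
  c(comparatives = sum(deg == "comparative", na.rm = TRUE),
    superlatives = sum(deg == "superlative", na.rm = TRUE))
}

#' @export
print.micro_report <- function(x, ...) {
  cat(sprintf("<micro-structure report for %s>\n", attr(x, "id")))
  df <- as.data.frame(x)
  for (i in seq_along(df)) {
    v <- df[[i]]
    cat(sprintf("  %-26s %s\n", names(df)[i],
                ifelse(is.na(v), "NA", format(round(v, 3)))))
  }
  invisible(x)
}

#' @export
as.data.frame.micro_report <- function(x, ...) {
  out <- as.data.frame(unclass(x)[MICRO_METRICS], stringsAsFactors = FALSE)
  cbind(data.frame(id = attr(x, "id"), stringsAsFactors = FALSE), out)
}

#' Write micro-structure reports to CSV
#'
#' One row per transcript; column names are the conventional metric labels
#' (Mean length of utterance (words) full transcript, ...).
#'
#' @param reports A list of `micro_report` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_micro_csv <- function(reports, path) {
  if (inherits(reports, "micro_report")) reports <- list(reports)
  df <- do.call(rbind, lapply(reports, as.data.frame))
  lab <- validation_icc_values("micro")
  names(df) <- c("id", lab$label[match(MICRO_METRICS, lab$metric)])
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Serialize a micro-structure report to JSON
#'
#' @param x A `micro_report`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string or `path` invisibly.
#' @export
micro_report_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "micro_report"))
  obj <- c(list(id = attr(x, "id")), unclass(x)[MICRO_METRICS])
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
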