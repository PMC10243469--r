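# Independent oracles used to cross-check the implementation.
#
# oracle_micro recounts every micro-structure metric with explicit
# token-by-token loops over the parsed (and tagged) transcript, sharing no
# aggregation code with compute_micro_report. oracle_icc recovers the
# variance components through stats::aov on the long-format layout rather
# than direct mean-square arithmetic.

oracle_micro <- function(t, lex, kw, xx_words = 2) {
  tk <- t$tokens
  child_utts <- t$utterances$index[t$utterances$speaker == "C"]
  lemma_of <- function(j) {
    lm <- if (!is.na(tk$intended[j])) tk$intended[j] else tk$base[j]
    tolower(lm)
  }
  word_w <- function(j) {
    if (tk$maze[j] || tk$clitic[j]) return(0)
    if (tk$unintelligible[j]) return(if (tk$surface[j] == "XX") xx_words else 1)
    1
  }
  morph_w <- function(j) {
    if (tk$maze[j]) return(0)
    if (tk$unintelligible[j]) return(if (tk$surface[j] == "XX") xx_words else 1)
    ntags <- if (nzchar(tk$morph[j]))
      length(strsplit(tk$morph[j], ",")[[1]]) else 0L
    1 + ntags
  }

  words <- c(); morphemes <- c()
  as_words <- c(); as_morphemes <- c()
  total_words <- 0; unint_w <- 0; int_w <- 0
  maze_spans <- 0L; questions <- 0L
  pos_tab <- c(noun = 0, pronoun = 0, verb = 0, rel_pronoun = 0, adverb = 0,
               adjective = 0, determiner = 0, particle = 0, preposition = 0,
               article = 0, conj_sub = 0, conj_coord = 0, copula_c = 0,
               copula_u = 0, aux_c = 0, aux_u = 0)
  bm <- c(regular_plurals = 0, irregular_plurals = 0, possessive_z = 0,
          regular_past_ed = 0, irregular_past = 0, third_person_regular = 0,
          third_person_irregular = 0, present_progressives = 0)
  comparatives <- 0L; superlatives <- 0L
  kw_n <- 0L; syn_n <- 0L
  types <- character(); n_type_tokens <- 0L

  for (u in child_utts) {
    rows <- which(tk$utt == u)
    uw <- 0; um <- 0
    prev_maze <- FALSE
    for (j in rows) {
      uw <- uw + word_w(j)
      um <- um + morph_w(j)
      if (tk$maze[j] && !prev_maze) maze_spans <- maze_spans + 1L
      prev_maze <- tk$maze[j]
      if (tk$maze[j]) next
      if (tk$unintelligible[j]) {
        unint_w <- unint_w + word_w(j)
        next
      }
      int_w <- int_w + word_w(j)
      lm <- lemma_of(j)
      types <- union(types, lm)
      n_type_tokens <- n_type_tokens + 1L
      if (lm %in% kw$keywords) kw_n <- kw_n + 1L
      if (lm %in% unlist(kw$synonyms)) syn_n <- syn_n + 1L
      p <- tk$pos[j]
      if (!is.na(p) && p %in% names(pos_tab))
        pos_tab[p] <- pos_tab[p] + 1
      tags <- if (nzchar(tk$morph[j])) strsplit(tk$morph[j], ",")[[1]]
      else character()
      if ("s" %in% tags) bm["regular_plurals"] <- bm["regular_plurals"] + 1
      if ("z" %in% tags) bm["possessive_z"] <- bm["possessive_z"] + 1
      if ("ed" %in% tags) bm["regular_past_ed"] <- bm["regular_past_ed"] + 1
      if ("3s" %in% tags)
        bm["third_person_regular"] <- bm["third_person_regular"] + 1
      if ("ing" %in% tags)
        bm["present_progressives"] <- bm["present_progressives"] + 1
      if (!length(tags)) {
        if (lm %in% lex$irregular_plurals)
          bm["irregular_plurals"] <- bm["irregular_plurals"] + 1
        if (lm %in% lex$irregular_pasts)
          bm["irregular_past"] <- bm["irregular_past"] + 1
        if (lm %in% lex$irregular_3rd)
          bm["third_person_irregular"] <- bm["third_person_irregular"] + 1
        if (!tk$clitic[j]) {
          d <- oracle_degree(lm, lex)
          if (identical(d, "comparative")) comparatives <- comparatives + 1L
          if (identical(d, "superlative")) superlatives <- superlatives + 1L
        }
      }
    }
    words <- c(words, uw); morphemes <- c(morphemes, um)
    term <- t$utterances$terminator[t$utterances$index == u]
    if (term == "?") questions <- questions + 1L
    in_as <- term != ">" && !any(tk$unintelligible[rows]) &&
      !any(tk$maze[rows])
    if (in_as) {
      as_words <- c(as_words, uw); as_morphemes <- c(as_morphemes, um)
    }
    total_words <- total_words + uw
  }

  out <- list(
    mlu_words_full = if (length(words)) mean(words) else NA_real_,
    mlu_morphemes_full = if (length(words)) mean(morphemes) else NA_real_,
    max_words_full = if (length(words)) max(words) else NA_real_,
    max_morphemes_full = if (length(words)) max(morphemes) else NA_real_,
    mlu_words_as = if (length(as_words)) mean(as_words) else NA_real_,
    mlu_morphemes_as = if (length(as_words)) mean(as_morphemes) else NA_real_,
    max_words_as = if (length(as_words)) max(as_words) else NA_real_,
    max_morphemes_as = if (length(as_words)) max(as_morphemes) else NA_real_,
    total_utterances = length(child_utts),
    total_words = total_words,
    keywords = kw_n, keyword_synonyms = syn_n,
    ttr = if (n_type_tokens) length(types) / n_type_tokens else NA_real_,
    nouns = unname(pos_tab["noun"]), pronouns = unname(pos_tab["pronoun"]),
    verbs = unname(pos_tab["verb"]),
    relative_pronouns = unname(pos_tab["rel_pronoun"]),
    adverbs = unname(pos_tab["adverb"]),
    adjectives = unname(pos_tab["adjective"]),
    determiners = unname(pos_tab["determiner"]),
    particles = unname(pos_tab["particle"]),
    prepositions = unname(pos_tab["preposition"]),
    present_progressives = unname(bm["present_progressives"]),
    questions = questions,
    subordinate_conjunctions = unname(pos_tab["conj_sub"]),
    coordinating_conjunctions = unname(pos_tab["conj_coord"]),
    regular_plurals = unname(bm["regular_plurals"]),
    irregular_plurals = unname(bm["irregular_plurals"]),
    possessive_z = unname(bm["possessive_z"]),
    articles = unname(pos_tab["article"]),
    regular_past_ed = unname(bm["regular_past_ed"]),
    irregular_past = unname(bm["irregular_past"]),
    third_person_regular = unname(bm["third_person_regular"]),
    third_person_irregular = unname(bm["third_person_irregular"]),
    unintelligible_words = unint_w,
    intelligibility_pct = if (int_w + unint_w > 0)
      100 * (1 - unint_w / (int_w + unint_w)) else NA_real_,
    maze_count = maze_spans,
    comparatives = comparatives, superlatives = superlatives,
    contractible_copula = unname(pos_tab["copula_c"]),
    uncontractible_copula = unname(pos_tab["copula_u"]),
    contractible_auxiliary = unname(pos_tab["aux_c"]),
    uncontractible_auxiliary = unname(pos_tab["aux_u"]),
    words_per_minute = if (!is.na(t$duration_s))
      total_words / (t$duration_s / 60) else NA_real_
  )
  out
}

# degree detection re-derived for the oracle
oracle_degree <- function(lm, lex) {
  if (lm %in% names(lex$comparatives_irregular)) return("comparative")
  if (lm %in% names(lex$superlatives_irregular)) return("superlative")
  strip <- function(suf) {
    stem <- substr(lm, 1, nchar(lm) - nchar(suf))
    if (nchar(stem) < 2) return(FALSE)
    cands <- c(stem, paste0(stem, "e"))
    if (substr(stem, nchar(stem), nchar(stem)) ==
        substr(stem, nchar(stem) - 1, nchar(stem) - 1))
      cands <- c(cands, substr(stem, 1, nchar(stem) - 1))
    if (endsWith(stem, "i"))
      cands <- c(cands, paste0(substr(stem, 1, nchar(stem) - 1), "y"))
    any(cands %in% lex$adjectives)
  }
  if (endsWith(lm, "est") && strip("est")) return("superlative")
  if (endsWith(lm, "er") && strip("er")) return("comparative")
  NA_character_
}

# ICC via variance components recovered from stats::aov
oracle_icc <- function(m, form) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(score = as.vector(m),
                  subj = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  two <- summary(stats::aov(score ~ subj + rater, data = d))[[1]]
  BMS <- two["subj", "Mean Sq"]
  JMS <- two["rater", "Mean Sq"]
  EMS <- two["Residuals", "Mean Sq"]
  one <- summary(stats::aov(score ~ subj, data = d))[[1]]
  WMS <- one["Residuals", "Mean Sq"]
  switch(form,
    ICC_1_1 = (BMS - WMS) / (BMS + (k - 1) * WMS),
    ICC_2_1 = (BMS - EMS) / (BMS + (k - 1) * EMS + k * (JMS - EMS) / n),
    ICC_3_1 = (BMS - EMS) / (BMS + (k - 1) * EMS)
  )
}

# small transcript builder for hand fixtures
tr <- function(..., id = "T1", age = 60, duration = NULL) {
  hdr <- c(paste0("@id: ", id), paste0("@age_months: ", age))
  if (!is.null(duration)) hdr <- c(hdr, paste0("@duration_s: ", duration))
  parse_transcript(c(hdr, ...))
}
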