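#' Deterministic lexicon-and-rule part-of-speech tagger
#'
#' Assigns exactly one part-of-speech label to every intelligible, non-maze
#' child token. The tagger is fully deterministic given the transcript and
#' lexicon, so metric tests are exact; a statistical tagger can be swapped
#' in behind the same interface for real data.
#'
#' Labels: `noun`, `pronoun`, `rel_pronoun`, `verb`, `adjective`, `adverb`,
#' `article`, `determiner`, `preposition`, `particle`, `conj_coord`,
#' `conj_sub`, `copula_c`, `copula_u`, `aux_c`, `aux_u` (BE forms, see
#' below), `aux_other`, `negation`, `wh`, `filler`, `unknown`.
#'
#' BE forms are resolved in context: a BE token followed (skipping adverbs,
#' negation and maze material) by a progressive-tagged verb or a lexicon
#' past participle is an auxiliary, otherwise a copula. Contracted clitics
#' (`'s`, `'re`, `'m`) are contractible; full present-tense `is`/`are`/`am`
#' are contractible unless utterance-initial (question inversion) or
#' utterance-final; `was`/`were`/`be`/`been`/`being` are uncontractible.
#'
#' A particle-verb pair from the lexicon (`pick` ... `up`) tags the particle
#' `particle` rather than `preposition` when the verb occurs at most three
#' tokens earlier with no intervening verb.
#'
#' Out-of-lexicon words are tagged `unknown` and recorded in
#' `attr(result, "unknown_words")`; tagging never fails on them.
#'
#' @param t A `transcript`.
#' @param lex A `lexicon` from [load_lexicon()].
#' @return The transcript with `tokens$pos` filled for child tokens.
#' @export
tag_pos <- function(t, lex) {
  stopifnot(inherits(t, "transcript"), inherits(lex, "lexicon"))
  tk <- t$tokens
  lemma <- tolower(ifelse(!is.na(tk$intended), tk$intended, tk$base))
  child <- child_token_mask(t)
  eligible <- child & !tk$maze & !tk$unintelligible
  pos <- rep(NA_character_, nrow(tk))
  unknown <- character()
  be_full <- c("am", "is", "are", "was", "were", "be", "been", "being")

  for (i in which(eligible)) {
    lm <- lemma[i]
    if (tk$clitic[i]) {
      pos[i] <- switch(tk$surface[i],
                       "'s" = , "'re" = , "'m" = "be",
                       "'ve" = , "'ll" = , "'d" = "aux_other",
                       "n't" = "negation", "unknown")
      next
    }
    tags <- strsplit(tk$morph[i], ",", fixed = TRUE)[[1]]
    if (any(tags %in% c("ing", "ed", "3s"))) { pos[i] <- "verb"; next }
    if (any(tags %in% c("s", "z"))) { pos[i] <- "noun"; next }
    if (lm %in% be_full) { pos[i] <- "be"; next }
    if (lm %in% lex$irregular_pasts || lm %in% lex$irregular_3rd) {
      pos[i] <- "verb"; next
    }
    if (lm %in% lex$irregular_plurals) { pos[i] <- "noun"; next }
    if (!is.na(detect_degree(lm, lex))) { pos[i] <- "adjective"; next }
    if (lm %in% lex$wh_words) { pos[i] <- "wh"; next }
    ranked <- lex$pos[[lm]]
    if (!is.null(ranked)) { pos[i] <- ranked[1] } else {
      pos[i] <- "unknown"; unknown <- c(unknown, lm)
    }
  }

  # contextual passes, per utterance
  for (u in unique(tk$utt[eligible])) {
    idx <- which(tk$utt == u & eligible)
    pos[idx] <- resolve_be(idx, pos[idx], tk, lemma, lex)
    pos[idx] <- resolve_particles(idx, pos[idx], lemma, lex)
  }

  t$tokens$pos <- pos
  attr(t, "unknown_words") <- unique(unknown)
  t
}

resolve_be <- function(idx, pos, tk, lemma, lex) {
  be_at <- which(pos == "be")
  for (b in be_at) {
    nxt <- b + 1L
    while (nxt <= length(idx) &&
           pos[nxt] %in% c("adverb", "negation", "filler")) nxt <- nxt + 1L
    is_aux <- FALSE
    if (nxt <= length(idx)) {
      j <- idx[nxt]
      tags <- strsplit(tk$morph[j], ",", fixed = TRUE)[[1]]
      if ("ing" %in% tags || lemma[j] %in% lex$past_participles)
        is_aux <- TRUE
    }
    i <- idx[b]
    contractible <- if (tk$clitic[i]) TRUE else {
      lm <- lemma[i]
      lm %in% c("is", "are", "am") && b != 1L && b != length(idx)
    }
    pos[b] <- paste0(if (is_aux) "aux" else "copula",
                     if (contractible) "_c" else "_u")
  }
  pos
}

resolve_particles <- function(idx, pos, lemma, lex) {
  for (p in which(pos == "preposition")) {
    back <- seq_len(min(3L, p - 1L))
    for (d in back) {
      q <- p - d
      if (pos[q] == "verb") {
        pair <- paste(lemma[idx[q]], lemma[idx[p]])
        if (pair %in% lex$particle_verbs) pos[p] <- "particle"
        break
      }
      if (startsWith(pos[q], "copula") || startsWith(pos[q], "aux")) break
    }
  }
  pos
}

# Comparative/superlative detection on a lemma: irregular maps first, then
# -er/-est suffix stripping with the stem required to be a lexicon
# adjective (blocks "river", "under"). Returns "comparative",
# "superlative" or NA.
detect_degree <- function(lm, lex) {
  if (lm %in% names(lex$comparatives_irregular)) return("comparative")
  if (lm %in% names(lex$superlatives_irregular)) return("superlative")
  for (kind in c("superlative", "comparative")) {
    suf <- if (kind == "superlative") "est" else "er"
    if (!endsWith(lm, suf)) next
    stem <- substr(lm, 1L, nchar(lm) - nchar(suf))
    if (nchar(stem) < 2L) next
    cands <- c(stem, paste0(stem, "e"))
    n <- nchar(stem)
    if (n >= 2L && substr(stem, n, n) == substr(stem, n - 1L, n - 1L))
      cands <- c(cands, substr(stem, 1L, n - 1L))
    if (endsWith(stem, "i"))
      cands <- c(cands, paste0(substr(stem, 1L, n - 1L), "y"))
    if (any(cands %in% lex$adjectives)) return(kind)
  }
  NA_character_
}
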