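#' Load a tagging lexicon
#'
#' The deterministic reference tagger is lexicon driven. A lexicon file is a
#' YAML document with a `pos` map (word to ranked part-of-speech labels, the
#' first label being the default), `particle_verbs` (verb/particle pairs
#' whose particle is tagged `particle` rather than `preposition`),
#' irregular-form sets (`irregular_plurals`, `irregular_pasts`,
#' `irregular_3rd`, `past_participles`), irregular degree maps
#' (`comparatives_irregular`, `superlatives_irregular`) and `wh_words`.
#'
#' @param path Path to a lexicon YAML file; `NULL` loads the bundled
#'   story-world lexicon.
#' @return A `lexicon` object (a validated list).
#' @export
load_lexicon <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "lexicon.yaml", package = "storysampler",
                        mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  for (f in c("pos", "particle_verbs", "irregular_plurals", "irregular_pasts",
              "irregular_3rd", "wh_words"))
    if (is.null(raw[[f]])) stop(sprintf("lexicon: missing field '%s'", f))
  pos <- lapply(raw$pos, as.character)
  if (any(lengths(pos) == 0L))
    stop("lexicon: every ranked POS list must be non-empty")
  lex <- list(
    pos = pos,
    particle_verbs = vapply(raw$particle_verbs,
                            function(p) paste(p, collapse = " "), ""),
    irregular_plurals = as.character(raw$irregular_plurals),
    irregular_pasts = as.character(raw$irregular_pasts),
    irregular_3rd = as.character(raw$irregular_3rd),
    past_participles = as.character(raw$past_participles),
    comparatives_irregular = unlist(raw$comparatives_irregular),
    superlatives_irregular = unlist(raw$superlatives_irregular),
    wh_words = as.character(raw$wh_words)
  )
  lex$adjectives <- names(pos)[vapply(pos, function(x) x[1] == "adjective",
                                      TRUE)]
  structure(lex, class = "lexicon")
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf("<lexicon: %d words, %d particle verbs, %d irregular pasts>\n",
              length(x$pos), length(x$particle_verbs),
              length(x$irregular_pasts)))
  invisible(x)
}

#' Load a keyword/synonym configuration
#'
#' Keywords are story-specific content lemmas whose use indicates recall of
#' the stimulus; synonyms are acceptable substitutes counted separately.
#' The file is YAML with a `keywords` list and a `synonyms` map (keyword to
#' list of substitute lemmas). Synonym sets must be disjoint from the
#' keyword set.
#'
#' @param path Path to a keyword YAML file; `NULL` loads the bundled
#'   treasure-quest example.
#' @return A `keyword_config` object with fields `keywords` and `synonyms`.
#' @export
load_keywords <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "keywords.yaml", package = "storysampler",
                        mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  kw <- as.character(raw$keywords)
  syn <- lapply(raw$synonyms, as.character)
  if (length(intersect(unlist(syn), kw)))
    stop("keyword config: synonym sets must be disjoint from keywords")
  structure(list(keywords = kw, synonyms = syn), class = "keyword_config")
}

#' @export
print.keyword_config <- function(x, ...) {
  cat(sprintf("<keyword config: %d keywords, %d synonym sets>\n",
              length(x$keywords), length(x$synonyms)))
  invisible(x)
}
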