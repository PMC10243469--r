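#' @title Story-grammar (macro-structure) scoring
#'
#' @description
#' Narrative macro-structure is scored over seven story-grammar elements —
#' setting, initiating event, internal response, plan, attempt, consequence
#' and character — each on a 0–3 scale (0 unobserved, 3 a full
#' demonstration), plus their 0–21 composite. Scoring is a transparent
#' cue-threshold engine over an editable rubric matrix: each element carries
#' per-level descriptors, a set of core cue phrases (the element's essential
#' realization) and a set of elaboration cue phrases (enriching detail).
#' Matching is at lemma level over non-maze child tokens; every match is
#' returned as an audit trail so a clinician can see exactly why a score
#' was given.
#'
#' @name macrostructure
NULL

MACRO_ELEMENTS <- c("setting", "initiating_event", "internal_response",
                    "plan", "attempt", "consequence", "character")

#' Load and validate a story-grammar rubric
#'
#' A rubric file is YAML with an `elements` map containing exactly the
#' seven story-grammar elements, each with `descriptors` for levels 0–3,
#' a non-empty `core_cues` list and a non-empty `elaboration_cues` list.
#'
#' @param path Path to a rubric YAML file; `NULL` loads the bundled
#'   treasure-quest rubric.
#' @return A `rubric_matrix` object.
#' @export
load_rubric <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "rubric.yaml", package = "storysampler",
                        mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  els <- raw$elements
  missing <- setdiff(MACRO_ELEMENTS, names(els))
  if (length(missing))
    stop("rubric schema error: missing element(s): ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(els), MACRO_ELEMENTS)
  if (length(extra))
    stop("rubric schema error: unknown element(s): ",
         paste(extra, collapse = ", "))
  for (e in MACRO_ELEMENTS) {
    el <- els[[e]]
    lv <- names(el$descriptors)
    if (!setequal(lv, c("0", "1", "2", "3")))
      stop(sprintf(
        "rubric schema error: element '%s' must have descriptors for levels 0-3 exactly",
        e))
    if (!length(el$core_cues) || !length(el$elaboration_cues))
      stop(sprintf("rubric schema error: element '%s' has an empty cue set", e))
  }
  structure(list(elements = els[MACRO_ELEMENTS]), class = "rubric_matrix")
}

#' @export
print.rubric_matrix <- function(x, ...) {
  cat("<story-grammar rubric: 7 elements, levels 0-3>\n")
  for (e in names(x$elements))
    cat(sprintf("  %-18s %d core / %d elaboration cues\n", e,
                length(x$elements[[e]]$core_cues),
                length(x$elements[[e]]$elaboration_cues)))
  invisible(x)
}

# Lemma sequences of the utterances searched for cues: non-maze child
# tokens (secondary-speaker material is excluded by default so parental
# scaffolding cannot inflate the child's score).
cue_corpus <- function(t, include_other = FALSE) {
  tk <- t$tokens
  ok <- !tk$maze & !tk$unintelligible
  if (!include_other) ok <- ok & child_token_mask(t)
  lemma <- tolower(token_lemma(t))
  lapply(unique(tk$utt[ok]), function(u) lemma[ok & tk$utt == u])
}

# Match one cue phrase (space-separated lemmas) against a list of lemma
# sequences; returns matched spans as "utt_pos" strings.
match_cue <- function(cue, corpus) {
  pat <- strsplit(tolower(cue), " ", fixed = TRUE)[[1]]
  hits <- character()
  for (ui in seq_along(corpus)) {
    seqs <- corpus[[ui]]
    n <- length(seqs); m <- length(pat)
    if (n < m) next
    for (s in seq_len(n - m + 1L))
      if (all(seqs[s:(s + m - 1L)] == pat))
        hits <- c(hits, sprintf("u%d@%d:%s", ui, s, cue))
  }
  hits
}

#' Score one story-grammar element
#'
#' Cue-threshold scoring: 0 when nothing matches; 1 when only elaboration
#' (partial) cues match; 2 when at least one core cue matches; 3 when core
#' cues plus at least `k_elaboration` elaboration cues match.
#'
#' @param t A `transcript`.
#' @param element One of the seven element names (see `MACRO_ELEMENTS`).
#' @param rubric A `rubric_matrix`.
#' @param k_elaboration Distinct elaboration cues required to lift a core
#'   realization from 2 to 3 (default 1).
#' @param include_other Also search secondary-speaker utterances
#'   (default `FALSE`).
#' @return List with `score` (integer 0–3) and `matched` (character vector
#'   of matched cue spans).
#' @export
score_element <- function(t, element, rubric, k_elaboration = 1,
                          include_other = FALSE) {
  stopifnot(inherits(t, "transcript"), inherits(rubric, "rubric_matrix"))
  element <- match.arg(element, MACRO_ELEMENTS)
  el <- rubric$elements[[element]]
  corpus <- cue_corpus(t, include_other)
  core_hits <- unlist(lapply(el$core_cues, match_cue, corpus = corpus))
  elab <- lapply(el$elaboration_cues, match_cue, corpus = corpus)
  n_elab_cues <- sum(lengths(elab) > 0L)
  elab_hits <- unlist(elab)
  score <- if (length(core_hits) && n_elab_cues >= k_elaboration) 3L
  else if (length(core_hits)) 2L
  else if (length(elab_hits)) 1L
  else 0L
  list(score = score, matched = c(core_hits, elab_hits))
}

#' Score all seven story-grammar elements
#'
#' @inheritParams score_element
#' @return A `macro_report`: list with `element_scores` (named integer
#'   vector), `composite` (their 0–21 sum) and `matched_cues` (per-element
#'   audit trail).
#' @examples
#' t <- parse_transcript(c("@id: P1", "@age_months: 66",
#'                         "C: one day the brave boy found a map ."))
#' score_macro(t, load_rubric())$element_scores
#' @export
score_macro <- function(t, rubric = load_rubric(), k_elaboration = 1,
                        include_other = FALSE) {
  res <- lapply(MACRO_ELEMENTS, function(e)
    score_element(t, e, rubric, k_elaboration, include_other))
  scores <- stats::setNames(vapply(res, `[[`, 0L, "score"), MACRO_ELEMENTS)
  structure(
    list(element_scores = scores, composite = sum(scores),
         matched_cues = stats::setNames(lapply(res, `[[`, "matched"),
                                        MACRO_ELEMENTS)),
    class = "macro_report", id = t$id)
}

#' @export
print.macro_report <- function(x, ...) {
  cat(sprintf("<story-grammar scores for %s>\n", attr(x, "id")))
  for (e in names(x$element_scores))
    cat(sprintf("  %-18s %d\n", e, x$element_scores[[e]]))
  cat(sprintf("  %-18s %d\n", "composite", x$composite))
  invisible(x)
}

#' @export
as.data.frame.macro_report <- function(x, ...) {
  out <- as.data.frame(as.list(x$element_scores))
  out$composite <- x$composite
  cbind(data.frame(id = attr(x, "id"), stringsAsFactors = FALSE), out)
}

#' Score a batch of transcripts
#'
#' Scores each transcript and returns a stable-order score table, one row
#' per transcript, suitable as a column block of a ratings table.
#' Per-transcript failures are caught: the row is kept with `NA` scores and
#' the error is recorded in `attr(, "failures")`.
#'
#' @param transcripts List of `transcript` objects (or paths parseable by
#'   [parse_transcript()]).
#' @inheritParams score_element
#' @return Data frame with columns `id`, the seven elements, `composite`.
#' @export
batch_score <- function(transcripts, rubric = load_rubric(),
                        k_elaboration = 1, include_other = FALSE) {
  empty <- cbind(
    data.frame(id = character(), stringsAsFactors = FALSE),
    as.data.frame(stats::setNames(rep(list(integer()), 8),
                                  c(MACRO_ELEMENTS, "composite"))))
  if (!length(transcripts)) return(structure(empty, failures = character()))
  rows <- vector("list", length(transcripts))
  failures <- character()
  for (i in seq_along(transcripts)) {
    tr <- transcripts[[i]]
    rows[[i]] <- tryCatch({
      if (!inherits(tr, "transcript")) tr <- parse_transcript(tr, is_path = TRUE)
      as.data.frame(score_macro(tr, rubric, k_elaboration, include_other))
    }, error = function(e) {
      failures <<- c(failures, sprintf("entry %d: %s", i, conditionMessage(e)))
      df <- as.data.frame(as.list(stats::setNames(rep(NA_integer_, 7),
                                                  MACRO_ELEMENTS)))
      df$composite <- NA_integer_
      cbind(data.frame(id = NA_character_, stringsAsFactors = FALSE), df)
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  out
}
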