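#' @title Annotated story-retell transcripts
#'
#' @description
#' A `transcript` holds one child's story retell as an ordered sequence of
#' utterances attributed to the child (`"C"`) or a secondary speaker (`"P"`,
#' typically a parent), with the annotation a trained transcriber adds during
#' transcript checking: maze (disfluency) spans, unintelligible stretches,
#' mispronunciation targets, bound-morpheme boundaries and an utterance
#' terminator.
#'
#' The plain-text dialect is line based:
#' \preformatted{
#' @id: P001
#' @age_months: 54
#' @duration_s: 108.0
#' C: the boy (um the) boy found a map .
#' P: what happen/ed next ?
#' C: he jump/ed over the wall>
#' }
#'
#' * Header lines `@id:` and `@age_months:` are required; `@duration_s:` is
#'   optional (recording length in seconds).
#' * Utterance lines start `C:` (child) or `P:` (secondary speaker).
#' * Mazes — fillers, repetitions, revisions — are parenthesised; maze words
#'   are kept in the transcript but excluded from language measures.
#' * Bound morphemes are tagged `/s` (plural), `/ed` (past), `/3s` (third
#'   person singular), `/z` (possessive), `/ing` (progressive).
#' * `X` marks one unintelligible word, `XX` an unintelligible stretch.
#' * `surface|intended` records a mispronunciation with its target form.
#' * Contracted forms are split into host plus clitic (`he's` becomes `he` +
#'   `'s`); the clitic is its own token.
#' * The terminator is `.` `?` `!`, or a trailing `>` for an utterance the
#'   child abandoned (incomplete).
#'
#' @details
#' Internally a `transcript` is a list with fields `id`, `age_months`,
#' `duration_s` (`NA` when not recorded), an `utterances` data frame
#' (`index`, `speaker`, `terminator`) and a `tokens` data frame (`utt`,
#' `surface`, `base`, `morph`, `intended`, `unintelligible`, `maze`,
#' `clitic`, `pos`). `base` is the surface form with morpheme tags stripped;
#' `pos` is filled by [tag_pos()].
#'
#' @name transcript
NULL

MORPH_TAGS <- c("s", "ed", "3s", "z", "ing")
TENSE_TAGS <- c("ed", "3s", "ing")
TERMINATORS <- c(".", "?", "!", ">")
CLITICS <- c("'s", "'re", "'m", "'ve", "'ll", "'d", "n't")

new_token_frame <- function(n = 0L) {
  data.frame(
    utt = integer(n), surface = character(n), base = character(n),
    morph = character(n), intended = rep(NA_character_, n),
    unintelligible = logical(n), maze = logical(n), clitic = logical(n),
    pos = rep(NA_character_, n), stringsAsFactors = FALSE
  )
}

new_transcript <- function(id, age_months, duration_s, utterances, tokens) {
  structure(
    list(id = id, age_months = as.integer(age_months),
         duration_s = duration_s, utterances = utterances, tokens = tokens),
    class = "transcript"
  )
}

#' Parse an annotated transcript document
#'
#' Reads the plain-text transcript dialect (see [transcript]) into a
#' `transcript` object. Parsing is strict: malformed lines raise an error
#' naming the offending line.
#'
#' @param text A single string, a character vector of lines, or a file path
#'   (when `is_path = TRUE`).
#' @param is_path Treat `text` as a file path and read it.
#' @return A `transcript` object.
#' @seealso [write_transcript()], [build_analysis_set()]
#' @examples
#' t <- parse_transcript(c("@id: P1", "@age_months: 54",
#'                         "C: he jump/ed over the wall ."))
#' t$tokens$morph
#' @export
parse_transcript <- function(text, is_path = FALSE) {
  if (is_path) text <- readLines(text, warn = FALSE, encoding = "UTF-8")
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]

  id <- NULL; age <- NULL; dur <- NA_real_
  speakers <- character(); terminators <- character()
  tok_cols <- list(); utt_i <- 0L

  for (ln in seq_along(text)) {
    line <- trimws(text[[ln]])
    if (!nzchar(line)) next
    if (startsWith(line, "@")) {
      m <- regmatches(line, regexec("^@([a-z_]+):\\s*(.*)$", line))[[1]]
      if (length(m) != 3L)
        stop(sprintf("line %d: malformed header line '%s'", ln, line))
      val <- trimws(m[3])
      switch(m[2],
        id = { id <- val },
        age_months = { age <- suppressWarnings(as.integer(val)) },
        duration_s = { dur <- suppressWarnings(as.numeric(val)) },
        stop(sprintf("line %d: unknown header field '@%s:'", ln, m[2]))
      )
      next
    }
    if (!grepl("^[CP]:", line))
      stop(sprintf("line %d: expected speaker prefix 'C:' or 'P:'", ln))
    body <- trimws(substr(line, 3L, nchar(line)))
    utt_i <- utt_i + 1L
    parsed <- parse_utterance_body(body, ln)
    if (!length(parsed$surface))
      stop(sprintf("line %d: utterance has no tokens", ln))
    parsed$utt <- rep(utt_i, length(parsed$surface))
    speakers[utt_i] <- substr(line, 1L, 1L)
    terminators[utt_i] <- parsed$terminator
    parsed$terminator <- NULL
    tok_cols[[utt_i]] <- parsed
  }

  if (is.null(id) || !nzchar(id))
    stop("metadata error: missing '@id:' header")
  if (is.null(age) || is.na(age))
    stop("metadata error: missing or non-integer '@age_months:' header")
  if (!is.na(dur) && dur <= 0)
    stop("metadata error: '@duration_s:' must be positive")

  utterances <- data.frame(index = seq_len(utt_i), speaker = speakers,
                           terminator = terminators,
                           stringsAsFactors = FALSE)
  tokens <- if (utt_i > 0L) {
    data.frame(
      utt = unlist(lapply(tok_cols, `[[`, "utt")),
      surface = unlist(lapply(tok_cols, `[[`, "surface")),
      base = unlist(lapply(tok_cols, `[[`, "base")),
      morph = unlist(lapply(tok_cols, `[[`, "morph")),
      intended = unlist(lapply(tok_cols, `[[`, "intended")),
      unintelligible = unlist(lapply(tok_cols, `[[`, "unintelligible")),
      maze = unlist(lapply(tok_cols, `[[`, "maze")),
      clitic = unlist(lapply(tok_cols, `[[`, "clitic")),
      pos = unlist(lapply(tok_cols, `[[`, "pos")),
      stringsAsFactors = FALSE)
  } else new_token_frame()
  rownames(tokens) <- NULL
  new_transcript(id, age, dur, utterances, tokens)
}

# Parse one utterance body (text after the speaker prefix) into token
# column vectors and a terminator. Raises with the line number on
# malformed markup.
parse_utterance_body <- function(body, ln) {
  pieces <- strsplit(body, "\\s+")[[1]]
  pieces <- pieces[nzchar(pieces)]
  terminator <- NA_character_
  in_maze <- FALSE
  surface <- character(); base <- character(); morph <- character()
  intended <- character(); unint <- logical(); maze <- logical()
  clitic <- logical()
  emit <- function(s, b, m, it, un, mz, cl) {
    surface <<- c(surface, s); base <<- c(base, b); morph <<- c(morph, m)
    intended <<- c(intended, it); unint <<- c(unint, un)
    maze <<- c(maze, mz); clitic <<- c(clitic, cl)
  }

  for (pi in seq_along(pieces)) {
    p <- pieces[[pi]]
    if (p %in% c(".", "?", "!", ">")) {
      if (pi != length(pieces))
        stop(sprintf("line %d: terminator '%s' not at end of utterance", ln, p))
      terminator <- p
      next
    }
    if (endsWith(p, ">")) {
      if (pi != length(pieces))
        stop(sprintf("line %d: '>' terminator not at end of utterance", ln))
      terminator <- ">"
      p <- substr(p, 1L, nchar(p) - 1L)
    }
    opens <- nchar(p) - nchar(sub("^\\(+", "", p))
    if (opens > 1L || (opens == 1L && in_maze))
      stop(sprintf("line %d: nested maze parenthesis", ln))
    if (opens == 1L) { in_maze <- TRUE; p <- sub("^\\(", "", p) }
    closes <- nchar(p) - nchar(sub("\\)+$", "", p))
    if (closes > 1L || (closes == 1L && !in_maze))
      stop(sprintf("line %d: unbalanced maze parenthesis", ln))
    if (closes == 1L) p <- sub("\\)$", "", p)
    if (!nzchar(p))
      stop(sprintf("line %d: empty token", ln))
    parse_word(p, in_maze, ln, emit)
    if (closes == 1L) in_maze <- FALSE
  }
  if (in_maze)
    stop(sprintf("line %d: maze parenthesis never closed", ln))
  if (is.na(terminator))
    stop(sprintf("line %d: missing utterance terminator (. ? ! or >)", ln))
  list(surface = surface, base = base, morph = morph, intended = intended,
       unintelligible = unint, maze = maze, clitic = clitic,
       pos = rep(NA_character_, length(surface)), terminator = terminator)
}

# One whitespace-delimited word -> one or two emitted tokens (host +
# clitic).
parse_word <- function(p, in_maze, ln, emit) {
  if (p %in% c("X", "XX")) {
    emit(p, NA_character_, "", NA_character_, TRUE, in_maze, FALSE)
    return(invisible())
  }
  intended <- NA_character_
  if (grepl("|", p, fixed = TRUE)) {
    parts <- strsplit(p, "|", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !nzchar(parts[1]) || !nzchar(parts[2]))
      stop(sprintf("line %d: malformed mispronunciation token '%s'", ln, p))
    p <- parts[1]; intended <- parts[2]
  }
  tags <- character()
  while (grepl("/", p, fixed = TRUE)) {
    tag <- sub("^.*/", "", p)
    if (!tag %in% MORPH_TAGS)
      stop(sprintf("line %d: unknown morpheme tag '/%s'", ln, tag))
    tags <- c(tag, tags)
    p <- sub("/[a-z0-9]+$", "", p)
    if (!nzchar(p))
      stop(sprintf("line %d: morpheme tag with empty stem", ln))
  }
  if (sum(tags %in% TENSE_TAGS) > 1L)
    stop(sprintf("line %d: more than one tense/agreement tag on one token", ln))

  host <- p; clitic <- NULL
  if (grepl("'", p, fixed = TRUE) && !startsWith(p, "'")) {
    if (grepl("n't$", p)) {
      host <- sub("n't$", "", p); clitic <- "n't"
    } else {
      apos <- max(gregexpr("'", p, fixed = TRUE)[[1]])
      host <- substr(p, 1L, apos - 1L)
      clitic <- substr(p, apos, nchar(p))
    }
    if (is.null(clitic) || !clitic %in% CLITICS) {
      host <- p; clitic <- NULL  # e.g. o'clock
    }
  }
  emit(host, host, paste(tags, collapse = ","), intended, FALSE, in_maze,
       FALSE)
  if (!is.null(clitic))
    emit(clitic, clitic, "", NA_character_, FALSE, in_maze, TRUE)
  invisible()
}

#' Serialize a transcript back to the dialect
#'
#' Writes a `transcript` as dialect text such that
#' `parse_transcript(write_transcript(t))` reproduces `t` exactly.
#'
#' @param t A `transcript`.
#' @param path Optional file path; when given the document is written there
#'   and returned invisibly.
#' @return Character vector of lines (invisibly when `path` is given).
#' @export
write_transcript <- function(t, path = NULL) {
  stopifnot(inherits(t, "transcript"))
  lines <- c(paste0("@id: ", t$id), paste0("@age_months: ", t$age_months))
  if (!is.na(t$duration_s))
    lines <- c(lines, paste0("@duration_s: ", format(t$duration_s)))
  tk <- t$tokens
  words <- tk$surface
  hastag <- nzchar(tk$morph) & !tk$unintelligible
  words[hastag] <- paste0(words[hastag], "/",
                          gsub(",", "/", tk$morph[hastag], fixed = TRUE))
  hasint <- !is.na(tk$intended)
  words[hasint] <- paste0(words[hasint], "|", tk$intended[hasint])
  by_utt <- split(seq_len(nrow(tk)),
                  factor(tk$utt, levels = t$utterances$index))
  for (i in seq_len(nrow(t$utterances))) {
    u <- t$utterances[i, ]
    rows <- by_utt[[i]]
    pieces <- character(); piece_maze <- logical()
    for (j in rows) {
      w <- words[j]
      if (tk$clitic[j] && length(pieces)) {
        pieces[length(pieces)] <- paste0(pieces[length(pieces)], w)
      } else {
        pieces <- c(pieces, w)
        piece_maze <- c(piece_maze, tk$maze[j])
      }
    }
    # wrap contiguous maze runs in parentheses
    if (any(piece_maze)) {
      r <- rle(piece_maze)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (k in seq_along(r$values)) {
        if (!r$values[k]) next
        pieces[starts[k]] <- paste0("(", pieces[starts[k]])
        pieces[ends[k]] <- paste0(pieces[ends[k]], ")")
      }
    }
    term <- u$terminator
    body <- if (term == ">") {
      paste0(paste(pieces, collapse = " "), ">")
    } else {
      paste(c(pieces, term), collapse = " ")
    }
    lines <- c(lines, paste0(u$speaker, ": ", body))
  }
  if (!is.null(path)) {
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(lines))
  }
  lines
}

#' Construct the analysis set of a transcript
#'
#' The analysis set contains the child utterances that remain after removing
#' incomplete utterances and utterances containing unintelligible segments
#' or mazes. Length metrics computed on the analysis set avoid crediting the
#' child with material inflated by disfluency or guessed content.
#'
#' @param t A `transcript` (or an existing analysis set, in which case the
#'   operation is idempotent).
#' @return A `transcript` subclassed `"analysis_set"` containing only the
#'   retained child utterances, reindexed contiguously; the original
#'   utterance indices are kept in `attr(, "source_index")`.
#' @export
build_analysis_set <- function(t) {
  stopifnot(inherits(t, "transcript"))
  keep <- integer()
  for (i in seq_len(nrow(t$utterances))) {
    u <- t$utterances[i, ]
    if (u$speaker != "C") next
    if (u$terminator == ">") next
    tk <- t$tokens[t$tokens$utt == u$index, , drop = FALSE]
    if (any(tk$unintelligible) || any(tk$maze)) next
    keep <- c(keep, u$index)
  }
  utter <- t$utterances[t$utterances$index %in% keep, , drop = FALSE]
  toks <- t$tokens[t$tokens$utt %in% keep, , drop = FALSE]
  remap <- stats::setNames(seq_along(keep), keep)
  utter$index <- as.integer(remap[as.character(utter$index)])
  toks$utt <- as.integer(remap[as.character(toks$utt)])
  rownames(utter) <- NULL; rownames(toks) <- NULL
  out <- new_transcript(t$id, t$age_months, t$duration_s, utter, toks)
  class(out) <- c("analysis_set", class(out))
  attr(out, "source_index") <- keep
  out
}

#' Flag transcripts unsuitable for language analysis
#'
#' Applies the quality screens a human checker would use before analysis:
#' the retell is too short, the secondary speaker dominates, or the child
#' never speaks. Thresholds are configurable because the original screens
#' were rater judgements.
#'
#' @param t A `transcript`.
#' @param min_words Minimum child word count (default 30).
#' @param max_other_frac Maximum tolerated fraction of utterances from the
#'   secondary speaker (default 0.5).
#' @return Character vector of flags, possibly empty: `"too_short"`,
#'   `"excess_secondary_speaker"`, `"no_child_utterances"`.
#' @export
validate_transcript <- function(t, min_words = 30, max_other_frac = 0.5) {
  stopifnot(inherits(t, "transcript"))
  flags <- character()
  n_child <- sum(t$utterances$speaker == "C")
  if (n_child == 0L) flags <- c(flags, "no_child_utterances")
  wc <- sum(token_word_weight(t)[child_token_mask(t) & !t$tokens$maze])
  if (n_child > 0L && wc < min_words) flags <- c(flags, "too_short")
  n_utt <- nrow(t$utterances)
  if (n_utt > 0L && (n_utt - n_child) / n_utt > max_other_frac)
    flags <- c(flags, "excess_secondary_speaker")
  flags
}

# Logical mask over t$tokens: token belongs to a child utterance.
child_token_mask <- function(t) {
  child_idx <- t$utterances$index[t$utterances$speaker == "C"]
  t$tokens$utt %in% child_idx
}

# Word weight per token: clitics merge into their host (weight 0), "XX"
# counts as `xx_words` words, everything else 1.
token_word_weight <- function(t, xx_words = 2) {
  w <- rep(1, nrow(t$tokens))
  w[t$tokens$clitic] <- 0
  w[t$tokens$unintelligible & t$tokens$surface == "XX"] <- xx_words
  w
}

# The lemma used by all analyses: the intended form of a mispronunciation,
# otherwise the tag-stripped base.
token_lemma <- function(t) {
  ifelse(!is.na(t$tokens$intended), t$tokens$intended, t$tokens$base)
}

#' @export
print.transcript <- function(x, ...) {
  n_child <- sum(x$utterances$speaker == "C")
  cat(sprintf("<transcript %s: age %d mo, %d utterances (%d child), %d tokens>\n",
              x$id, x$age_months, nrow(x$utterances), n_child, nrow(x$tokens)))
  invisible(x)
}

#' @export
print.analysis_set <- function(x, ...) {
  cat(sprintf("<analysis set of %s: %d child utterances retained>\n",
              x$id, nrow(x$utterances)))
  invisible(x)
}

#' Read or write a transcript as a one-token-per-row CSV
#'
#' Long-form CSV carries the same information as the dialect text: header
#' metadata is repeated on every row; columns are `id`, `age_months`,
#' `duration_s`, `utt`, `speaker`, `terminator`, `surface`, `base`, `morph`,
#' `intended`, `unintelligible`, `maze`, `clitic`, `pos`.
#'
#' @param t A `transcript`.
#' @param path CSV file path.
#' @return `read_transcript_csv()` returns a `transcript`;
#'   `write_transcript_csv()` returns `path` invisibly.
#' @export
write_transcript_csv <- function(t, path) {
  stopifnot(inherits(t, "transcript"))
  u <- t$utterances
  df <- cbind(
    data.frame(id = t$id, age_months = t$age_months,
               duration_s = t$duration_s, stringsAsFactors = FALSE),
    t$tokens[, c("utt", "surface", "base", "morph", "intended",
                 "unintelligible", "maze", "clitic", "pos")]
  )
  df$speaker <- u$speaker[match(df$utt, u$index)]
  df$terminator <- u$terminator[match(df$utt, u$index)]
  df <- df[, c("id", "age_months", "duration_s", "utt", "speaker",
               "terminator", "surface", "base", "morph", "intended",
               "unintelligible", "maze", "clitic", "pos")]
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_transcript_csv
#' @export
read_transcript_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        colClasses = "character")
  stopifnot(nrow(df) > 0L)
  toks <- new_token_frame(nrow(df))
  toks$utt <- as.integer(df$utt)
  toks$surface <- df$surface
  toks$base <- df$base
  toks$morph <- ifelse(is.na(df$morph), "", df$morph)
  toks$intended <- df$intended
  toks$unintelligible <- df$unintelligible == "TRUE"
  toks$maze <- df$maze == "TRUE"
  toks$clitic <- df$clitic == "TRUE"
  toks$pos <- df$pos
  uidx <- !duplicated(df$utt)
  utter <- data.frame(index = as.integer(df$utt[uidx]),
                      speaker = df$speaker[uidx],
                      terminator = df$terminator[uidx],
                      stringsAsFactors = FALSE)
  new_transcript(df$id[1], as.integer(df$age_months[1]),
                 suppressWarnings(as.numeric(df$duration_s[1])),
                 utter, toks)
}
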