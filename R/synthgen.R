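#' @title Seeded synthetic data with known ground truth
#'
#' @description
#' Generators for every artifact the analysis modules consume: dialect-valid
#' story-retell transcripts with age-graded length and secondary-speaker
#' scaffolding, participant rosters with planted exclusion flags,
#' deprivation-rank tables with planted partial-area ranks, and two-rater
#' score tables with a known intraclass correlation. All vocabulary is
#' drawn from the same closed treasure-quest story world as the bundled
#' lexicon, keyword list and rubric, so every planted feature count is
#' exact by construction and recorded in a ground-truth record.
#'
#' @name synthgen
NULL

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
  }
  expr
}

# --- story-world building blocks ------------------------------------------

# Macro-element realizations. Each level-1 utterance carries elaboration
# cues only, level 2 the core cue, level 3 core plus elaboration; cue
# inventories are shared with inst/extdata/rubric.yaml.
MACRO_TEMPLATES <- list(
  setting = list(core = c("one", "day", "they", "went", "to", "the", "beach"),
                 elab = c("it", "was", "a", "sunny", "morning")),
  initiating_event = list(core = c("he", "found", "a", "map"),
                          elab = c("the", "map", "was", "in", "the", "sand")),
  internal_response = list(core = c("the", "boy", "was", "excited"),
                           elab = c("he", "really", "want/ed", "the",
                                    "treasure")),
  plan = list(core = c("he", "decide/ed", "to", "dig"),
              elab = c("it", "was", "a", "good", "idea")),
  attempt = list(core = c("he", "dug", "a", "hole"),
                 elab = c("he", "try/ed", "again", "and", "again")),
  consequence = list(core = c("he", "open/ed", "the", "chest"),
                     elab = c("at", "last", "he", "smile/ed")),
  character = list(core = c("the", "brave", "boy", "had", "a", "dog"),
                   elab = c("an", "old", "man", "was", "his", "friend"))
)

MORPH_TEMPLATES <- list(
  s = c("he", "saw", "two", "bird/s"),
  ed = c("she", "walk/ed", "to", "the", "door"),
  ing = c("he", "is", "jump/ing"),
  `3s` = c("she", "climb/3s", "the", "hill"),
  z = c("he", "saw", "the", "bird/z", "nest"),
  irregular_past = c("they", "went", "to", "the", "tree"),
  irregular_plural = c("he", "saw", "the", "men"),
  irregular_3rd = c("he", "has", "a", "boat"),
  comparative = c("the", "tree", "is", "taller"),
  superlative = c("this", "tree", "is", "the", "tallest"),
  contraction = c("he's", "jump/ing")
)

OTHER_TEMPLATES <- list(
  c("what", "happen/ed", "next", "?"),
  c("tell", "me", "more", "."),
  c("and", "then", "what", "?"),
  c("did", "he", "find", "it", "?"),
  c("that", "is", "good", ".")
)

FILLER <- list(
  subj = c("he", "she", "they"),
  verb_past = c("walk/ed", "jump/ed", "climb/ed", "look/ed", "smile/ed",
                "shout/ed"),
  prep = c("over", "to", "on", "near", "across"),
  noun = c("rock", "door", "path", "hill", "tree", "bird", "river", "boat"),
  adj = c("big", "small", "red", "tall", "dark", "deep"),
  adv = c("quickly", "slowly", "then", "there")
)

pick <- function(x) x[[sample.int(length(x), 1L)]]

# Filler sentence of exactly n words, avoiding every rubric cue bigram.
filler_sentence <- function(n) {
  if (n <= 1L) return(pick(c("look", "run")))
  if (n == 2L) return(c(pick(FILLER$subj), pick(FILLER$verb_past)))
  if (n == 3L) return(c(pick(FILLER$subj), pick(FILLER$verb_past),
                        pick(FILLER$adv)))
  if (n >= 4L && stats::runif(1) < 0.25)
    return(c("and", filler_sentence(n - 1L)))
  if (n == 5L && stats::runif(1) < 0.3)
    return(c(pick(FILLER$subj), pick(FILLER$verb_past), "because",
             pick(FILLER$subj), pick(FILLER$verb_past)))
  if (n == 4L) return(c(pick(FILLER$subj), pick(FILLER$verb_past), "the",
                        pick(FILLER$noun)))
  c(pick(FILLER$subj), pick(FILLER$verb_past), pick(FILLER$prep), "the",
    sample(FILLER$adj, n - 5L, replace = TRUE), pick(FILLER$noun))
}

utt_words <- function(words, maze) {
  w <- ifelse(maze, 0, ifelse(words == "XX", 2, 1))
  sum(w)
}

# --- transcript generator -------------------------------------------------

#' Generate one synthetic story-retell transcript
#'
#' Emits a dialect-valid transcript whose every annotated feature (bound
#' morphemes, mazes, unintelligible stretches, mispronunciations, keywords,
#' story-grammar cue material, secondary-speaker turns) is planted at a
#' known location, together with a ground-truth record of the exact counts.
#' Defaults follow the age-graded profile of the validation sample
#' ([retell_norms()]): word-count mean and SD per age band, and
#' secondary-speaker utterance counts that decline with age.
#'
#' @param seed Integer seed; identical seeds give identical output.
#' @param age_months Child age in months (48–95 for in-frame ages).
#' @param target_words Child word-count target; `NULL` draws from the age
#'   band's normative distribution (minimum 20).
#' @param maze_rate Probability an utterance receives a maze insertion.
#' @param unintelligible_rate Probability a filler utterance has one word
#'   replaced by `X`.
#' @param incomplete_rate Probability a filler utterance is marked
#'   incomplete (`>`).
#' @param mispronunciation_rate Probability a filler noun is realized as a
#'   mispronunciation with its target form.
#' @param question_rate Probability a filler utterance is a question.
#' @param secondary_mean Mean number of secondary-speaker utterances;
#'   `NULL` uses the age band's normative mean and SD.
#' @param planted_macro_levels Named integer vector (0–3 per story-grammar
#'   element); `NULL` draws each level uniformly from 0–3.
#' @param keyword_prob,synonym_prob Per-keyword/per-synonym probability of
#'   planting a mention.
#' @param morph_lambda Poisson mean for extra plantings of each morphology
#'   template.
#' @param duration_missing_rate Probability the duration header is absent.
#' @param id Participant id written to the header.
#' @return List with `transcript` (parsed), `lines` (the dialect document)
#'   and `truth` (ground-truth counts: word count, per-tag morpheme counts,
#'   maze spans, unintelligible tokens, keyword/synonym mentions, planted
#'   macro levels, utterance counts).
#' @examples
#' g <- gen_transcript(seed = 1, age_months = 60)
#' g$truth$macro_levels
#' @export
gen_transcript <- function(seed = NULL, age_months = 60,
                           target_words = NULL, maze_rate = 0.15,
                           unintelligible_rate = 0.05,
                           incomplete_rate = 0.05,
                           mispronunciation_rate = 0.02,
                           question_rate = 0.05, secondary_mean = NULL,
                           planted_macro_levels = NULL, keyword_prob = 0.4,
                           synonym_prob = 0.2, morph_lambda = 1,
                           duration_missing_rate = 0.018, id = "SYN001") {
  rates <- c(maze_rate, unintelligible_rate, incomplete_rate,
             mispronunciation_rate, question_rate, keyword_prob,
             synonym_prob, duration_missing_rate)
  if (any(rates < 0 | rates > 1))
    stop("probabilities must lie in [0, 1]")
  with_seed(seed, {
    norms <- retell_norms()
    bi <- match(age_band_for(age_months), norms$band)
    if (is.na(bi)) bi <- if (age_months < 48) 1L else nrow(norms)
    if (is.null(target_words))
      target_words <- max(20, round(stats::rnorm(1, norms$words_mean[bi],
                                                 norms$words_sd[bi])))
    if (target_words <= 0) stop("word-count target must be positive")

    kw <- load_keywords()
    levels <- planted_macro_levels
    if (is.null(levels))
      levels <- stats::setNames(sample(0:3, 7, replace = TRUE),
                                MACRO_ELEMENTS)
    levels <- levels[MACRO_ELEMENTS]
    if (any(is.na(levels)) || any(levels < 0) || any(levels > 3))
      stop("planted_macro_levels must cover all 7 elements with levels 0-3")

    mk <- function(words, term = ".")
      list(words = words, maze = rep(FALSE, length(words)), term = term,
           speaker = "C")

    macro_utts <- list()
    for (e in MACRO_ELEMENTS) {
      tpl <- MACRO_TEMPLATES[[e]]
      lv <- levels[[e]]
      if (lv == 1L) macro_utts <- c(macro_utts, list(mk(tpl$elab)))
      if (lv >= 2L) macro_utts <- c(macro_utts, list(mk(tpl$core)))
      if (lv == 3L) macro_utts <- c(macro_utts, list(mk(tpl$elab)))
    }

    opt_utts <- list()
    for (k in kw$keywords)
      if (stats::runif(1) < keyword_prob)
        opt_utts <- c(opt_utts, list(mk(c("he", "saw", "the", k))))
    for (s in unlist(kw$synonyms))
      if (stats::runif(1) < synonym_prob)
        opt_utts <- c(opt_utts, list(mk(c("she", "saw", "the", s))))
    for (tpl in MORPH_TEMPLATES) {
      times <- stats::rpois(1, morph_lambda)
      for (r in seq_len(min(times, 3L)))
        opt_utts <- c(opt_utts, list(mk(tpl)))
    }

    budget <- function(utts) sum(vapply(utts, function(u)
      utt_words(u$words, u$maze), 0))
    used <- budget(macro_utts) + budget(opt_utts)
    # trim optional plantings when the target is short
    while (used > target_words && length(opt_utts)) {
      drop <- sample.int(length(opt_utts), 1L)
      used <- used - utt_words(opt_utts[[drop]]$words,
                               opt_utts[[drop]]$maze)
      opt_utts[[drop]] <- NULL
    }

    filler_utts <- list()
    remaining <- target_words - used
    while (remaining > 0L) {
      n <- if (remaining <= 8L) remaining else sample(4:8, 1L)
      u <- mk(filler_sentence(n))
      if (stats::runif(1) < question_rate) u$term <- "?"
      else if (stats::runif(1) < incomplete_rate) u$term <- ">"
      if (stats::runif(1) < unintelligible_rate && length(u$words) > 1L) {
        j <- sample.int(length(u$words), 1L)
        u$words[j] <- "X"
      }
      if (stats::runif(1) < mispronunciation_rate) {
        nn <- which(u$words %in% FILLER$noun)
        if (length(nn)) {
          j <- nn[1]
          u$words[j] <- paste0("w", substr(u$words[j], 2L,
                                           nchar(u$words[j])),
                               "|", u$words[j])
        }
      }
      filler_utts <- c(filler_utts, list(u))
      remaining <- remaining - utt_words(u$words, u$maze)
    }

    others <- c(opt_utts, filler_utts)
    if (length(others)) others <- others[sample.int(length(others))]
    child_utts <- interleave_keeping_order(macro_utts, others)

    # maze insertions (maze tokens never break cue adjacency because cue
    # matching skips them)
    for (i in seq_along(child_utts)) {
      if (stats::runif(1) < maze_rate) {
        u <- child_utts[[i]]
        span <- sample(list("um", c("um", "the"), "uh"), 1L)[[1]]
        at <- sample.int(length(u$words) + 1L, 1L) - 1L
        u$words <- append(u$words, span, after = at)
        u$maze <- append(u$maze, rep(TRUE, length(span)), after = at)
        child_utts[[i]] <- u
      }
    }

    sec_mean <- secondary_mean
    sec_sd <- NULL
    if (is.null(sec_mean)) {
      sec_mean <- norms$secondary_mean[bi]; sec_sd <- norms$secondary_sd[bi]
    }
    n_other <- draw_count(sec_mean, sec_sd)
    other_utts <- lapply(seq_len(n_other), function(i) {
      tpl <- pick(OTHER_TEMPLATES)
      list(words = tpl[-length(tpl)], maze = rep(FALSE, length(tpl) - 1L),
           term = tpl[length(tpl)], speaker = "P")
    })
    all_utts <- interleave_keeping_order(child_utts, other_utts)

    duration <- NA_real_
    if (stats::runif(1) >= duration_missing_rate)
      duration <- round(max(30, stats::rnorm(1, norms$duration_mean[bi],
                                             norms$duration_sd[bi])), 1)

    lines <- c(paste0("@id: ", id), paste0("@age_months: ", age_months))
    if (!is.na(duration)) lines <- c(lines, paste0("@duration_s: ",
                                                   format(duration)))
    for (u in all_utts) lines <- c(lines, render_utt(u))

    truth <- tally_truth(all_utts, levels, kw)
    truth$target_words <- target_words
    list(transcript = parse_transcript(lines), lines = lines, truth = truth)
  })
}

# counts drawn to match a configured mean exactly in expectation; an SD
# larger than Poisson switches to negative binomial
draw_count <- function(mean, sd = NULL) {
  if (mean <= 0) return(0L)
  if (!is.null(sd) && !is.na(sd) && sd^2 > mean) {
    size <- mean^2 / (sd^2 - mean)
    return(stats::rnbinom(1, size = size, mu = mean))
  }
  stats::rpois(1, mean)
}

interleave_keeping_order <- function(ordered, rest) {
  n <- length(ordered) + length(rest)
  if (n == 0L) return(list())
  pos <- sort(sample.int(n, length(ordered)))
  out <- vector("list", n)
  out[pos] <- ordered
  out[setdiff(seq_len(n), pos)] <- rest
  out
}

render_utt <- function(u) {
  pieces <- u$words
  if (any(u$maze)) {
    r <- rle(u$maze)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      pieces[starts[k]] <- paste0("(", pieces[starts[k]])
      pieces[ends[k]] <- paste0(pieces[ends[k]], ")")
    }
  }
  body <- if (u$term == ">") paste0(paste(pieces, collapse = " "), ">")
  else paste(c(pieces, u$term), collapse = " ")
  paste0(u$speaker, ": ", body)
}

tally_truth <- function(utts, levels, kw) {
  tags <- c(s = 0L, ed = 0L, `3s` = 0L, z = 0L, ing = 0L)
  mazes <- 0L; unint <- 0L; kws <- 0L; syns <- 0L; words <- 0
  n_child <- 0L; n_other <- 0L; incomplete <- 0L; questions <- 0L
  for (u in utts) {
    if (u$speaker != "C") { n_other <- n_other + 1L; next }
    n_child <- n_child + 1L
    if (u$term == ">") incomplete <- incomplete + 1L
    if (u$term == "?") questions <- questions + 1L
    if (any(u$maze)) mazes <- mazes + sum(rle(u$maze)$values)
    for (j in seq_along(u$words)) {
      if (u$maze[j]) next
      w <- u$words[j]
      if (w %in% c("X", "XX")) { unint <- unint + 1L; words <- words +
        if (w == "XX") 2 else 1; next }
      words <- words + 1
      if (grepl("|", w, fixed = TRUE))
        w <- strsplit(w, "|", fixed = TRUE)[[1]][2]
      for (tg in names(tags))
        tags[tg] <- tags[tg] + sum(grepl(paste0("/", tg, "(/|$)"), w))
      base <- sub("/.*$", "", sub("'.*$", "", w))
      if (base %in% kw$keywords) kws <- kws + 1L
      if (base %in% unlist(kw$synonyms)) syns <- syns + 1L
    }
  }
  list(word_count = words, morph = tags, maze_spans = mazes,
       unintelligible_tokens = unint, keywords = kws, synonyms = syns,
       macro_levels = levels, n_child_utterances = n_child,
       n_other_utterances = n_other, incomplete_utterances = incomplete,
       questions = questions)
}

# --- roster generator -----------------------------------------------------

#' Generate a synthetic participant roster
#'
#' Builds a demographically valid roster with planted exclusion flags. A
#' `mix` entry that is an integer of 1 or more plants that exact number of
#' rows failing the corresponding flow stage (each on distinct rows, in
#' pipeline order, so staged exclusion counts equal the plants exactly); a
#' value below 1 is a per-row probability instead.
#'
#' @param n Roster size.
#' @param seed Integer seed.
#' @param mix Named list with any of `non_gb`, `not_completed`,
#'   `language_disability`, `bilingual`, `not_audible`, `unsuitable`.
#' @param partial_postcodes Pool of partial postcode areas to sample from.
#' @return List with `roster` (data frame) and `truth` (planted counts).
#' @examples
#' r <- gen_roster(100, seed = 1, mix = list(non_gb = 10))
#' sum(r$roster$nation == "other")
#' @export
gen_roster <- function(n, seed = NULL, mix = list(),
                       partial_postcodes = sprintf("Z%02d", 1:20)) {
  stopifnot(n > 0)
  known <- c("non_gb", "not_completed", "language_disability", "bilingual",
             "not_audible", "unsuitable")
  unknown <- setdiff(names(mix), known)
  if (length(unknown))
    stop("unknown mix field(s): ", paste(unknown, collapse = ", "))
  with_seed(seed, {
    roster <- data.frame(
      id = sprintf("P%05d", seq_len(n)),
      age_months = sample(48:95, n, replace = TRUE),
      sex = sample(c("M", "F"), n, replace = TRUE),
      partial_postcode = sample(partial_postcodes, n, replace = TRUE),
      nation = sample(UK_NATIONS, n, replace = TRUE,
                      prob = c(0.84, 0.05, 0.08, 0.03)),
      english_first_language = TRUE, monolingual = TRUE,
      disability_flag = FALSE, completed_tasks = TRUE, audible = TRUE,
      analysis_suitable = NA, stringsAsFactors = FALSE
    )
    roster$country <- roster$nation

    counts <- lapply(known, function(f) {
      v <- mix[[f]]
      if (is.null(v)) return(0L)
      if (v >= 1) as.integer(v) else stats::rbinom(1, n, v)
    })
    names(counts) <- known
    if (sum(unlist(counts)) > n)
      stop("planted mix counts exceed roster size")

    at <- 0L
    take <- function(k) { idx <- at + seq_len(k); at <<- at + k; idx }
    i <- take(counts$non_gb)
    roster$nation[i] <- "other"; roster$country[i] <- "other"
    i <- take(counts$not_completed); roster$completed_tasks[i] <- FALSE
    i <- take(counts$language_disability)
    roster$english_first_language[i] <- FALSE
    i <- take(counts$bilingual); roster$monolingual[i] <- FALSE
    i <- take(counts$not_audible); roster$audible[i] <- FALSE
    i <- take(counts$unsuitable); roster$analysis_suitable[i] <- FALSE

    roster <- roster[sample.int(n), , drop = FALSE]
    rownames(roster) <- NULL
    list(roster = roster, truth = counts)
  })
}

# --- ratings generator ----------------------------------------------------

#' Generate a two-rater score table with known agreement
#'
#' Each subject's two scores share a latent subject effect with variance
#' `rho` plus independent noise with variance `1 - rho`, so the expected
#' two-way random absolute-agreement ICC is `rho`.
#'
#' @param n Number of subjects (at least 2).
#' @param rho Target intraclass correlation, in \[0, 1).
#' @param seed Integer seed.
#' @return A `ratings_table` with raters `tool` and `rater`.
#' @export
gen_ratings <- function(n, rho, seed = NULL) {
  if (n < 2) stop("need at least 2 subjects")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  with_seed(seed, {
    s <- stats::rnorm(n, 0, sqrt(rho))
    m <- cbind(s + stats::rnorm(n, 0, sqrt(1 - rho)),
               s + stats::rnorm(n, 0, sqrt(1 - rho)))
    ratings_table(m, raters = c("tool", "rater"))
  })
}

# --- deprivation table generator ------------------------------------------

#' Generate a synthetic deprivation-rank table
#'
#' Assigns a permutation of ranks 1..N to synthetic full postcode areas
#' grouped into partial areas. Specific ranks can be planted on a named
#' partial area through `partial_map`, which makes the quintile of that
#' area exact by construction.
#'
#' @param nation Nation label for the table.
#' @param N Total ranked areas (at least 5).
#' @param seed Integer seed.
#' @param partial_map Optional named list: partial area to the exact rank
#'   vector of its full areas.
#' @param areas_per_partial Full areas per auto-generated partial area.
#' @return An `imd_table`.
#' @examples
#' imd <- gen_imd_table(N = 100, seed = 1,
#'                      partial_map = list(AB1 = c(5, 10, 15)))
#' quintile_for_partial_postcode("AB1", imd)
#' @export
gen_imd_table <- function(nation = "England", N = 100, seed = NULL,
                          partial_map = NULL, areas_per_partial = 5) {
  stopifnot(N >= 5)
  with_seed(seed, {
    planted <- unlist(partial_map)
    if (any(duplicated(planted)) || any(planted < 1) || any(planted > N))
      stop("partial_map ranks must be distinct and within 1..N")
    rows <- list()
    for (pa in names(partial_map)) {
      rk <- partial_map[[pa]]
      rows[[pa]] <- data.frame(nation = nation, partial = pa,
                               postcode = paste(pa, seq_along(rk)),
                               rank = as.integer(rk),
                               stringsAsFactors = FALSE)
    }
    rest <- setdiff(seq_len(N), planted)
    rest <- rest[sample.int(length(rest))]
    grp <- ceiling(seq_along(rest) / areas_per_partial)
    for (g in unique(grp)) {
      pa <- sprintf("Z%02d", g)
      rk <- rest[grp == g]
      rows[[pa]] <- data.frame(nation = nation, partial = pa,
                               postcode = paste(pa, seq_along(rk)),
                               rank = rk, stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    rownames(df) <- NULL
    imd_table(df, N = stats::setNames(as.integer(N), nation))
  })
}
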