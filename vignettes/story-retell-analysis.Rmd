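---
title: "Methods: story-retell language sample analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: story-retell language sample analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(storysampler)
```

This vignette is the package's own account of its methods: what is
computed, under which conventions, which choices were genuinely open and
how they were settled, and what the bundled synthetic data can and cannot
establish.

## The transcript model and its conventions

A story retell is transcribed as utterance lines attributed to the child
(`C:`) or a secondary speaker (`P:`, usually a parent). Utterance
segmentation is an annotation-time act: the human checker decides where
utterances end, and the parser trusts line breaks — there is no automatic
re-segmentation. The annotation layer carries exactly what the metrics
need:

* **Mazes** (fillers, repetitions, revisions) in parentheses. Maze tokens
  are retained in the document but excluded from every word, morpheme,
  word-class, keyword and cue count; the count of maze *spans* is itself
  a metric.
* **Bound morphemes** tagged `/s` (plural), `/ed` (past), `/3s` (third
  person singular), `/z` (possessive), `/ing` (progressive). A token
  carries at most one tense/agreement tag.
* **Unintelligible speech**: `X` for one word, `XX` for a stretch. How
  many words a stretch contributes is genuinely undecidable from the
  transcript, so it is a parameter (`xx_words`, default 2).
* **Mispronunciations** as `surface|intended`. All analyses use the
  intended form: the metrics target language, not articulation.
* **Contractions** split into host plus clitic (`he's` → `he` + `'s`).
  The clitic is a token of its own (one morpheme) but zero additional
  words, so `he's` is one word and two morphemes. This split is what lets
  contracted BE forms feed the copula/auxiliary metrics.
* **Terminators** `.` `?` `!` and `>` for an utterance the child
  abandoned. Questions are counted by terminator alone, because
  punctuation is human-verified upstream.

The **analysis set** removes child utterances that are incomplete or
contain any maze or unintelligible token. Length metrics are reported
over both the full transcript and the analysis set; the analysis set is
the stricter estimate of what the child produces fluently.

Undefined quantities are reported as `NA`, never 0 — a transcript with no
child utterances has no MLU, and 0 would be a valid (different) value.

## The tagger

The bundled tagger is lexicon-and-rule based and fully deterministic, so
every metric test can be exact. The interface is pluggable: for real
recordings a statistical tagger can be substituted without touching the
metric code, at the cost of exactness in testing.

Rules, in order: clitic identity; tense/agreement tags force `verb` and
nominal tags force `noun`; BE forms; lexicon irregular sets (pasts,
third-person, plurals); degree-form detection; ranked lexicon lookup;
`unknown` otherwise (logged, never fatal). Two context passes follow:

* **Copula vs auxiliary BE**: a BE form followed — skipping adverbs,
  negation and maze material — by a progressive-tagged verb or a lexicon
  past participle is an auxiliary; otherwise a copula. **Contractibility**
  is a Brown-convention approximation: clitics are contractible; full
  `is/are/am` are contractible unless utterance-initial (question
  inversion) or utterance-final; `was/were/be/been/being` are
  uncontractible. The field names these categories without publishing
  decision rules, so the rules here are explicit and documented rather
  than claimed to match any other tool token-for-token.
* **Particles**: a preposition-form word within three tokens after a verb
  forms a particle verb when the (verb, word) pair is in the lexicon's
  particle list (`picked up` vs `jumped over`). Irregular pasts are
  listed as pair heads in their own right (`dug up`).

Degree forms accept `-er`/`-est` only when the stem (allowing final-`e`,
doubled-consonant and `y`→`i` spelling changes) is a lexicon adjective —
`bigger` counts, `river` does not — plus the irregular maps
(`better/best`, `more/most`, `worse/worst`).

## Micro-structure metrics

All 44 metrics are computed in one pass (`compute_micro_report()`).
Conventions that were open and are now fixed:

* **Total words** excludes maze tokens and counts unintelligible tokens
  at their word mass (`X` = 1, `XX` = `xx_words`); mazes are reported
  separately rather than folded into length.
* **Type–token ratio** is computed over the full transcript's non-maze
  intelligible child tokens, on lemma forms (tag-stripped bases,
  mispronunciation targets), matching the full-transcript default of the
  other lexical counts.
* **Intelligibility** is `100 (1 − unintelligible / (intelligible +
  unintelligible))` over child non-maze word mass.
* **Words per minute** requires a recorded duration and is `NA` without
  one.

## Story-grammar scoring

The original tool's trained macro-structure classifier is not
reproducible from public information (no training data, no model
description), and the package's clinical audience explicitly rejects
black-box scores. The scorer here is therefore a transparent
cue-threshold engine over the same 0–3 semantics: per element, 0 when
nothing matches, 1 when only elaboration (partial) cues match, 2 when a
core cue matches, 3 when core plus at least `k_elaboration` (default 1)
distinct elaboration cues match. Cues are lemma-level phrase patterns
matched within utterances over non-maze child tokens; every match is
returned as an audit trail. Scores are monotone in transcript content by
construction: adding text can only add matches.

Two consequences are worth stating plainly. First, the bundled rubric is
*illustrative*: the refined element descriptors that trained human raters
used are unpublished, so the shipped cue inventories cover the bundled
treasure-quest story world, and a real deployment would author its own
rubric config. Second, secondary-speaker utterances are excluded from cue
matching by default (`include_other = FALSE`): parents scaffold retells
("where were they going?"), and scaffolded elements should not credit the
child.

## Reliability

ICCs are computed from the two-way mean-squares decomposition
(single-rater Shrout–Fleiss forms). The validation literature for this
kind of tool rarely names its ICC form; the package therefore makes the
form a required, recorded parameter and defaults to ICC(2,1) — two-way
random, absolute agreement — the stricter, conventional choice when the
tool and a human are meant to be interchangeable raters. Missing cells
are handled by listwise deletion with the retained `n` recorded.
Degenerate inputs are errors, not numbers: fewer than two complete
subjects, or a table with zero variance everywhere.

Bands follow the conventional cut-points, read literally from their usual
statement "good (0.70–0.90), excellent (>0.90)": good is closed at both
ends, so 0.90 itself is good; moderate is [0.50, 0.70); poor is below
0.50. Percent agreement is the share of subjects whose two scores differ
by at most a tolerance (default 0), the form used for rubric scores.

## Sampling frame and participant flow

The frame crosses six age bands (4;0–4;5, 4;6–4;11, 5;0–5;5, 5;6–5;11,
6;0–6;11, 7;0–7;11), five deprivation quintiles and sex at 10 per cell —
20 per band-by-quintile, 100 per band, 600 total. Deprivation comes from
partial postcodes: the national deprivation ranks of all full postcode
areas within the partial area are averaged, and the mean rank is binned
into equal-rank fifths — quintile *q* covers mean ranks in
((q−1)N/5, qN/5] with N the nation's ranked-area count. Rank 1 (and so
quintile 1) is the most deprived; this orientation is a recorded
convention, and the mapping is invariant to rescaling ranks and N
together. A partial area matching two nations' tables is an error, since
ranks are not comparable across nations.

The flow pipeline applies named filters in order — country, task
completion, language/disability, audibility, analysis suitability — and
records excluded/remaining at each stage, with conservation (in =
excluded + out) guaranteed. The published flow for this design is itself
arithmetically inconsistent at one stage (the language/disability and
audibility counts do not subtract cleanly), so the module deliberately
reports whatever the data imply rather than forcing any printed total.
Thresholds for "too short" and "too much secondary-speaker input" in
`validate_transcript()` were originally rater judgements; defaults here
(30 words, 50% secondary-speaker utterances) are package choices.

## The synthetic-data generator

The generator emulates the study conditions so that every other module is
testable without any real recordings:

* **Age-graded length**: word-count targets are drawn per age band from
  the validation sample's normative means and SDs (≈136 words at 4;0–4;5
  rising to ≈168 at 7;0–7;11), and the assembly hits the drawn target
  exactly (filler sentences of exact residual length), up to rare
  overflow when the planted story material alone exceeds a short target.
* **Scaffolding**: secondary-speaker utterance counts are drawn with the
  band's normative mean and SD (negative-binomial when overdispersed),
  falling from ≈11.4 at age 4 to ≈2.4 at age 7.
* **Annotation noise**: per-utterance maze insertion (default rate 0.15),
  unintelligible substitution (0.05), incomplete marking (0.05),
  mispronunciation (0.02) and child questions (0.05). These rates are not
  published anywhere; they were chosen once as plausible for young
  children's retells and are parameters, not claims.
* **Planted structure**: story-grammar levels per element (default:
  uniform 0–3), realized from the same cue inventories as the bundled
  rubric; keyword and morphology plantings with tallied counts. The
  ground-truth record contains exact counts of every planted feature, and
  filler vocabulary is chosen so it cannot form cue phrases.

What the generator does *not* emulate — and hence what green tests do not
show about real data: disfluency structure beyond simple maze spans,
speech-recognition error patterns, developmental grammar (no error
morphology like overregularised pasts), semantic coherence, or rubric
cue inventories beyond the bundled story world. Passing tests establish
that the machinery computes its definitions exactly, not that the bundled
lexicon or rubric generalises to real recordings.

## Numerical and testing choices

Determinism everywhere: the tagger and scorer have no randomness, and all
generator randomness sits behind one seed with the caller's RNG state
restored. ICC implementations are cross-checked against variance
components recovered independently via `stats::aov` to 1e-12; simulated
two-rater tables recover their target ICC within ±0.03 at n = 2,000. The
test suite runs the micro-metric oracle comparison on 500 generated
transcripts, parser round-trips on 1,000, and story-grammar label
recovery on 200 (≥95% exact element agreement, residual disagreement
being accidental cue matches in random text); these sizes give the
property checks comfortable power while keeping the default suite around
three minutes. The acceptance script uses 200 planted transcripts and 300
round-trips for the same properties.

## Known limitations

* The tagger's coverage is its lexicon; out-of-lexicon words are counted
  as `unknown` and appear in no word-class metric.
* Contractibility and copula/auxiliary rules are conventions, not learned
  behaviour; borderline cases (emphatic full forms, ellipsis) follow the
  documented rule even where a human coder might differ.
* The rubric engine is cue-based: paraphrases outside the cue inventory
  score as absent. That is the intended trade against opacity, and the
  audit trail makes every score inspectable.
* Real deprivation tables are not redistributable; the package generates
  synthetic ones and accepts real ones in the same CSV schema.
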