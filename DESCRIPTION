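Package: storysampler
Title: Story-Retell Language Sample Analysis and Reliability Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing young children's story-retell language
    samples from annotated transcripts: a plain-text transcript dialect
    with maze, unintelligible-speech, mispronunciation and bound-morpheme
    markup; a deterministic lexicon-and-rule part-of-speech tagger; 44
    micro-structure metrics (mean length of utterance in words and
    morphemes, type-token ratio, grammatical morphology, copula and
    auxiliary BE forms, and more) over the full transcript and the
    cleaned analysis set; transparent 0-3 rubric scoring of the seven
    story-grammar macro-structure elements; intraclass correlation and
    percent-agreement reliability with conventional reliability bands;
    stratified sampling by age band, sex and deprivation quintile with
    participant-flow accounting; and a seeded synthetic-data generator
    producing transcripts, rosters, deprivation-rank tables and rater
    score tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
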