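metric,label,icc
mlu_words_full,Mean length of utterance (words) full transcript,0.911
mlu_morphemes_full,Mean length of utterance (morphemes) full transcript,0.832
max_words_full,Max length of utterance (words) full transcript,0.986
max_morphemes_full,Max length of utterance (morphemes) full transcript,0.954
mlu_words_as,Mean length of utterance (words) analysis set,0.904
mlu_morphemes_as,Mean length of utterance (morphemes) analysis set,0.924
max_words_as,Max length of utterance (words) analysis set,0.755
max_morphemes_as,Max length of utterance (morphemes) analysis set,0.793
total_utterances,Total utterances,1.000
total_words,Total words,0.998
keywords,Keywords,0.987
keyword_synonyms,Synonyms of keywords,0.912
ttr,Type-token ratio,0.955
nouns,Nouns,0.975
pronouns,Pronouns,0.998
verbs,Verbs,0.987
relative_pronouns,Relative pronouns,0.213
adverbs,Adverbs,0.884
adjectives,Adjectives,0.949
determiners,Determiners,0.970
particles,Particles,0.850
prepositions,Prepositions,0.965
present_progressives,Present progressives,0.434
questions,Questions,0.986
subordinate_conjunctions,Subordinate conjunctions,0.772
coordinating_conjunctions,Coordinating conjunctions,1.000
regular_plurals,Regular -s plurals,0.995
irregular_plurals,Irregular plurals,0.664
possessive_z,`s possessive,0.843
articles,Articles,0.999
regular_past_ed,Regular past tense (-ed),0.968
irregular_past,Irregular past tense,0.984
third_person_regular,"Third person regular, present tense",0.934
third_person_irregular,"Third person irregular, present tense",0.986
unintelligible_words,Unintelligible words,0.999
intelligibility_pct,Intelligibility,0.998
maze_count,Count of mazes,1.000
comparatives,Comparatives,0.973
superlatives,Superlatives,0.990
contractible_copula,Contractible copula,0.957
uncontractible_copula,Uncontractible copula,0.955
contractible_auxiliary,Contractible auxiliary,0.904
uncontractible_auxiliary,Uncontractible auxiliary,0.870
words_per_minute,Words per minute,0.927
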