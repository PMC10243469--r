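# Example keyword/synonym configuration for the treasure-quest story.
# The study's own lists are unpublished; these cover the same story world.
keywords: [map, treasure, chest, parrot, island, cave, key]
synonyms:
  treasure: [gold, coin]
  map: [chart]
  cave: [tunnel]
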