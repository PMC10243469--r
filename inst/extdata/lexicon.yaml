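# Closed story-world lexicon for the treasure-quest retell.
# pos: word -> ranked part-of-speech labels (first label is the default).
pos:
  the: [article]
  a: [article]
  an: [article]
  this: [determiner]
  that: [determiner, rel_pronoun]
  these: [determiner]
  those: [determiner]
  some: [determiner]
  every: [determiner]
  one: [determiner]
  two: [determiner]
  his: [determiner]
  he: [pronoun]
  she: [pronoun]
  it: [pronoun]
  they: [pronoun]
  i: [pronoun]
  you: [pronoun]
  we: [pronoun]
  him: [pronoun]
  them: [pronoun]
  me: [pronoun]
  her: [pronoun]
  who: [rel_pronoun]
  which: [rel_pronoun]
  boy: [noun]
  dog: [noun]
  map: [noun]
  treasure: [noun]
  island: [noun]
  boat: [noun]
  cave: [noun]
  chest: [noun]
  gold: [noun]
  wall: [noun]
  beach: [noun]
  parrot: [noun]
  key: [noun]
  door: [noun]
  day: [noun]
  sea: [noun]
  sand: [noun]
  story: [noun]
  man: [noun]
  men: [noun]
  child: [noun]
  children: [noun]
  foot: [noun]
  feet: [noun]
  friend: [noun]
  morning: [noun]
  plan: [noun, verb]
  hole: [noun]
  idea: [noun]
  coin: [noun]
  rock: [noun]
  path: [noun]
  hill: [noun]
  tree: [noun]
  bird: [noun]
  river: [noun]
  nest: [noun]
  lad: [noun]
  chart: [noun]
  tunnel: [noun]
  home: [noun]
  house: [noun]
  lots: [noun]
  jump: [verb]
  run: [verb]
  ran: [verb]
  walk: [verb]
  look: [verb]
  find: [verb]
  found: [verb]
  open: [verb]
  climb: [verb]
  dig: [verb]
  dug: [verb]
  sail: [verb]
  see: [verb]
  saw: [verb]
  go: [verb]
  went: [verb]
  want: [verb]
  need: [verb]
  think: [verb]
  thought: [verb]
  say: [verb]
  said: [verb]
  take: [verb]
  took: [verb]
  taken: [verb]
  fall: [verb]
  fell: [verb]
  get: [verb]
  got: [verb]
  come: [verb]
  came: [verb]
  pick: [verb]
  give: [verb]
  gave: [verb]
  help: [verb]
  try: [verb]
  decide: [verb]
  cross: [verb]
  hide: [verb]
  hid: [verb]
  hidden: [verb]
  gone: [verb]
  broken: [verb]
  shout: [verb]
  smile: [verb]
  make: [verb]
  made: [verb]
  work: [verb]
  believe: [verb]
  start: [verb]
  have: [verb]
  has: [verb]
  does: [verb]
  big: [adjective]
  small: [adjective]
  happy: [adjective]
  sad: [adjective]
  old: [adjective]
  dark: [adjective]
  scared: [adjective]
  brave: [adjective]
  shiny: [adjective]
  golden: [adjective]
  little: [adjective]
  tall: [adjective]
  deep: [adjective]
  red: [adjective]
  secret: [adjective]
  sunny: [adjective]
  excited: [adjective]
  good: [adjective]
  hard: [adjective]
  last: [adjective]
  far: [adjective]
  long: [adjective]
  quickly: [adverb]
  slowly: [adverb]
  then: [adverb]
  very: [adverb]
  really: [adverb]
  suddenly: [adverb]
  carefully: [adverb]
  away: [adverb]
  there: [adverb]
  finally: [adverb]
  again: [adverb]
  first: [adverb]
  ago: [adverb]
  in: [preposition]
  "on": [preposition]
  over: [preposition]
  under: [preposition]
  to: [preposition]
  with: [preposition]
  at: [preposition]
  into: [preposition]
  behind: [preposition]
  across: [preposition]
  near: [preposition]
  of: [preposition]
  up: [preposition]
  down: [preposition]
  out: [preposition]
  "off": [preposition]
  and: [conj_coord]
  but: [conj_coord]
  or: [conj_coord]
  so: [conj_coord]
  because: [conj_sub]
  when: [conj_sub]
  while: [conj_sub]
  after: [conj_sub]
  before: [conj_sub]
  do: [aux_other]
  did: [aux_other]
  can: [aux_other]
  could: [aux_other]
  will: [aux_other]
  would: [aux_other]
  not: [negation]
  um: [filler]
  uh: [filler]
  er: [filler]
  oh: [filler]
# Particle pairs are listed per surface base form, so irregular pasts
# appear alongside their stems.
particle_verbs:
  - [pick, up]
  - [climb, up]
  - [dig, up]
  - [dug, up]
  - [take, out]
  - [took, out]
  - [fall, down]
  - [fell, down]
  - [run, off]
  - [ran, off]
  - [get, out]
  - [got, out]
  - [go, up]
  - [went, up]
irregular_plurals: [men, children, feet]
irregular_pasts: [went, saw, ran, found, took, fell, got, said, came, gave,
                  dug, hid, thought, made, had]
irregular_3rd: [has, does]
past_participles: [hidden, gone, broken, taken]
comparatives_irregular: {better: good, more: many, worse: bad}
superlatives_irregular: {best: good, most: many, worst: bad}
wh_words: [what, where, why, how]
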