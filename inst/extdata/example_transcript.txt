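@id: DEMO01
@age_months: 62
@duration_s: 96.5
C: one day they went to the beach .
C: the brave boy had a dog .
C: he found a map (um the) in the sand .
C: the boy was excited .
C: he really want/ed the treasure .
P: what happen/ed next ?
C: he decide/ed to dig .
C: he dug a hole with his foot .
C: he try/ed again and again .
C: then he open/ed the chest .
C: at last he smile/ed .
C: there was lots of gold>
C: he's happy because he found the treasure .
C: the dog saw a X .
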