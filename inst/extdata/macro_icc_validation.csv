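element,label,icc
setting,Setting,0.850
initiating_event,Initiating event,0.898
internal_response,Internal response,0.577
plan,Plan,0.841
attempt,Attempt,0.616
consequence,Consequence,0.729
character,Character,0.939
composite,"Composite macro-structure ""story grammar"" score",0.928
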