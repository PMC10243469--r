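# Default story-grammar rubric for the treasure-quest retell (illustrative).
# Each element is scored 0-3: 0 = unobserved; 1 = partial (elaboration-type
# material only); 2 = core realization present; 3 = core plus elaboration.
# Cues are lemma-level phrase patterns matched over non-maze child tokens.
elements:
  setting:
    descriptors:
      "0": "No reference to time or place."
      "1": "Vague or partial reference to time or place."
      "2": "States where or when the story happens."
      "3": "Elaborated setting with time and place detail."
    core_cues: ["one day", "at the beach", "on an island"]
    elaboration_cues: ["sunny morning", "far away", "long ago"]
  initiating_event:
    descriptors:
      "0": "No initiating event."
      "1": "Hints at the discovery without stating it."
      "2": "States the event that starts the quest."
      "3": "Initiating event with circumstantial detail."
    core_cues: ["found a map", "saw a map"]
    elaboration_cues: ["in the sand", "behind a rock"]
  internal_response:
    descriptors:
      "0": "No reference to a character's feelings or thoughts."
      "1": "Implied feeling without naming it."
      "2": "Names the character's feeling about the event."
      "3": "Feeling plus its motivating force."
    core_cues: ["was excited", "was happy", "was scared"]
    elaboration_cues: ["really want", "could not believe"]
  plan:
    descriptors:
      "0": "No plan stated."
      "1": "Goal implied but no plan."
      "2": "States what the character decides to do."
      "3": "Plan with reasoning or evaluation."
    core_cues: ["decide to", "make a plan", "made a plan"]
    elaboration_cues: ["good idea", "think about"]
  attempt:
    descriptors:
      "0": "No attempt described."
      "1": "Motion toward the goal without an attempt."
      "2": "Describes an action taken toward the goal."
      "3": "Attempt with effort or repetition detail."
    core_cues: ["dug a hole", "sail to the island", "climb the wall"]
    elaboration_cues: ["try again", "work hard"]
  consequence:
    descriptors:
      "0": "No outcome given."
      "1": "Outcome implied only."
      "2": "States the outcome of the attempt."
      "3": "Outcome with resolution detail."
    core_cues: ["open the chest", "found the treasure", "got the gold"]
    elaboration_cues: ["at last", "gold coin"]
  character:
    descriptors:
      "0": "No character identified."
      "1": "Generic reference to a person or animal."
      "2": "Identifies a main character."
      "3": "Main character plus supporting character detail."
    core_cues: ["the brave boy", "the little parrot"]
    elaboration_cues: ["his friend", "old man"]
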