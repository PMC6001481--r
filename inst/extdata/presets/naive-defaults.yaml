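preset: naive-defaults
structure_mix:
  intransitive: 0.3333333333333333
  transitive: 0.3333333333333333
  dative: 0.3333333333333334
kind_weights:
  DEF: 1
  INDEF: 1
  PROX: 1
  DIST: 1
number_weights:
  SING: 8
  TWO: 1
  THREE: 1
  PLUR: 1
tense_past_prob: 0.5
aspect_prog_prob: 0.5
phrasal_verb_prob: 0.5
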