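# Mechanized form of the manual exclusion pass.
# pairs: a query is dropped when BOTH the trigger word and the context word
#   occur among its normalized tokens (pets, irrelevant organs).
# phrases: a query is dropped when the normalized phrase occurs as a
#   consecutive word sequence in the normalized query text.
pairs:
  - {trigger: cat, context: bleeding}
  - {trigger: cat, context: pain}
  - {trigger: cat, context: vomiting}
  - {trigger: cat, context: diarrhoea}
  - {trigger: dog, context: bleeding}
  - {trigger: dog, context: pain}
  - {trigger: dog, context: vomiting}
  - {trigger: dog, context: diarrhoea}
  - {trigger: kitten, context: bleeding}
  - {trigger: puppy, context: bleeding}
  - {trigger: finger, context: bleeding}
  - {trigger: finger, context: pain}
  - {trigger: toe, context: pain}
  - {trigger: elbow, context: pain}
  - {trigger: gum, context: bleeding}
  - {trigger: nose, context: bleeding}
phrases:
  - club music
  - night club
  - golf club
  - book club
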