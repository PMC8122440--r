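# Sentence templates for the synthetic corpus generator. Tokens of the form
# kind:group are slots; slots sharing a group letter agree in gender and
# number, verbs agree in number with their group's noun. Plain tokens are
# literals. Kinds: det, noun, adj, inv (invariant adjective), verb, haber,
# part (participle), hom (homophone-bearing word), num (number mask).
templates:
  - "det:S noun:S verb:S tras det:O noun:O adj:O ."
  - "det:S noun:S adj:S verb:S det:O noun:O ."
  - "se verb:O det:O noun:O adj:O en det:P noun:P ."
  - "det:S noun:S haber:S part det:O noun:O adj:O ."
  - "det:S noun:S verb:S el hom de det:O noun:O ."
  - "hoy verb:O det:O noun:O adj:O y det:P noun:P adj:P ."
  - "det:S noun:S verb:S num años con dolor inv:X ."
  - "se verb:O a det:O noun:O tras det:P noun:P ."
  - "det:S noun:S no verb:S det:O noun:O inv:O ."
  - "det:S noun:S verb:S muy bien tras det:O noun:O ."
  - "det:S noun:S adj:S haber:S part det:O noun:O ."
  - "se verb:O det:O noun:O y det:P noun:P adj:P ."
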