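# Regular-verb person terminations for the three Spanish conjugation classes,
# for present, past and future tense in indicative and subjunctive mood.
# Six entries per paradigm: persons 1..6 (yo, tú, él/ella, nosotros,
# vosotros, ellos/ellas). "past" is the imperfect paradigm; note that its
# 1st and 3rd person singular terminations coincide, as they do in Spanish.
# Accented terminations are stored with their accents.
classes:
  ar:
    indicative:
      present: [o, as, a, amos, áis, an]
      past: [aba, abas, aba, ábamos, abais, aban]
      future: [aré, arás, ará, aremos, aréis, arán]
    subjunctive:
      present: [e, es, e, emos, éis, en]
      past: [ara, aras, ara, áramos, arais, aran]
      future: [are, ares, are, áremos, areis, aren]
  er:
    indicative:
      present: [o, es, e, emos, éis, en]
      past: [ía, ías, ía, íamos, íais, ían]
      future: [eré, erás, erá, eremos, eréis, erán]
    subjunctive:
      present: [a, as, a, amos, áis, an]
      past: [iera, ieras, iera, iéramos, ierais, ieran]
      future: [iere, ieres, iere, iéremos, iereis, ieren]
  ir:
    indicative:
      present: [o, es, e, imos, ís, en]
      past: [ía, ías, ía, íamos, íais, ían]
      future: [iré, irás, irá, iremos, iréis, irán]
    subjunctive:
      present: [a, as, a, amos, áis, an]
      past: [iera, ieras, iera, iéramos, ierais, ieran]
      future: [iere, ieres, iere, iéremos, iereis, ieren]
# Full conjugation of the auxiliary haber (irregular, listed as whole words).
haber:
  indicative:
    present: [he, has, ha, hemos, habéis, han]
    past: [había, habías, había, habíamos, habíais, habían]
    future: [habré, habrás, habrá, habremos, habréis, habrán]
  subjunctive:
    present: [haya, hayas, haya, hayamos, hayáis, hayan]
    past: [hubiera, hubieras, hubiera, hubiéramos, hubierais, hubieran]
    future: [hubiere, hubieres, hubiere, hubiéremos, hubiereis, hubieren]
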