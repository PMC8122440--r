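# Synthetic clinical-Spanish mini-lexicon.
# Every paradigm lists all the forms the rule groups can reach from any of
# its members (closure), so that the real-word gate cannot starve a group.

# genre x number paradigms: [masc_sg, fem_sg, masc_pl, fem_pl]
nouns4:
  - [enfermero, enfermera, enfermeros, enfermeras]
  - [médico, médica, médicos, médicas]
  - [interno, interna, internos, internas]

# fixed-gender nouns: [singular, plural, gender]
nouns:
  - [paciente, pacientes, m]
  - [caso, casos, m]
  - [vaso, vasos, m]
  - [peso, pesos, m]
  - [masa, masas, f]
  - [zona, zonas, f]
  - [herida, heridas, f]
  - [prueba, pruebas, f]
  - [fiebre, fiebres, f]
  - [dolor, dolores, m]
  - [tumor, tumores, m]
  - [control, controles, m]
  - [nivel, niveles, m]
  - [año, años, m]
  - [ecografía, ecografías, f]
  - [analítica, analíticas, f]
  - [planta, plantas, f]
  - [sangrado, sangrados, m]
  - [cultivo, cultivos, m]
  - [abdomen, abdómenes, m]

# adjective paradigms: [masc_sg, fem_sg, masc_pl, fem_pl]; the masculine
# singulars carry the listed genre suffixes (-ado, -ido, -ano, -ino, -ico,
# -ito, -oso, -ero, -ario, -ento, -olo)
adjectives:
  - [conservado, conservada, conservados, conservadas]
  - [inflamado, inflamada, inflamados, inflamadas]
  - [infectado, infectada, infectados, infectadas]
  - [controlado, controlada, controlados, controladas]
  - [operado, operada, operados, operadas]
  - [unido, unida, unidos, unidas]
  - [definido, definida, definidos, definidas]
  - [dolorido, dolorida, doloridos, doloridas]
  - [sano, sana, sanos, sanas]
  - [fino, fina, finos, finas]
  - [masculino, masculina, masculinos, masculinas]
  - [femenino, femenina, femeninos, femeninas]
  - [crónico, crónica, crónicos, crónicas]
  - [quístico, quística, quísticos, quísticas]
  - [séptico, séptica, sépticos, sépticas]
  - [clínico, clínica, clínicos, clínicas]
  - [doloroso, dolorosa, dolorosos, dolorosas]
  - [fibroso, fibrosa, fibrosos, fibrosas]
  - [venoso, venosa, venosos, venosas]
  - [edematoso, edematosa, edematosos, edematosas]
  - [ligero, ligera, ligeros, ligeras]
  - [severo, severa, severos, severas]
  - [urinario, urinaria, urinarios, urinarias]
  - [solitario, solitaria, solitarios, solitarias]
  - [purulento, purulenta, purulentos, purulentas]
  - [sanguinolento, sanguinolenta, sanguinolentos, sanguinolentas]
  - [solo, sola, solos, solas]
  - [pequeñito, pequeñita, pequeñitos, pequeñitas]

# invariant modifiers: [singular, plural]
invariant_adjectives:
  - [leve, leves]
  - [grave, graves]
  - [estable, estables]
  - [abdominal, abdominales]
  - [general, generales]

# regular verbs: [infinitive, conjugation class]; the lexicon lists the
# full regular paradigm of each (36 finite forms) plus the four participle
# forms
verbs:
  - [presentar, ar]
  - [llevar, ar]
  - [tratar, ar]
  - [curar, ar]
  - [mejorar, ar]
  - [operar, ar]
  - [realizar, ar]
  - [pelear, ar]
  - [notar, ar]
  - [usar, ar]
  - [comer, er]
  - [beber, er]
  - [deber, er]
  - [responder, er]
  - [toser, er]
  - [vivir, ir]
  - [sufrir, ir]
  - [subir, ir]

# homophone pairs; both members are attested so the b/v, ll/y and silent-h
# rules can pass the real-word gate
homophones:
  - [uso, huso]
  - [tubo, tuvo]
  - [echo, hecho]
  - [haya, halla]
  - [vaso, baso]
  - [a, ha]
  - [e, he]

function_words: [el, la, los, las, un, una, unos, unas, de, del, en, con,
  sin, por, para, se, no, que, y, o, a, e, al, su, sus, más, muy, tras,
  sobre, hoy, bien]
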