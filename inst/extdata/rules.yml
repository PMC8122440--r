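# Rule tables for the morphological real-word error generators.

# Grammatical-genre suffix bases. For each base B the masculine/feminine
# singular pair is B+o / B+a and the plural pair is B+os / B+as; rules swap a
# matched suffix for its opposite-genre counterpart in the same number, in
# both directions.
genre_suffix_bases: [er, an, ad, in, id, ic, it, os, ari, ent, ol]

# Number endings. Singular words ending in a listed vowel take +s, those
# ending in a listed consonant take +es; plural words ending in vowel+s drop
# the s, those ending in consonant+es drop the es.
number_vowel_endings: [o, e, a]
number_consonant_endings: [d, n, l, j, r]
number_plural_endings: [os, es, as]

# Words ignored by the sentence-level error driver: high-frequency
# determiners, possessives, demonstratives and (multi-letter) prepositions
# whose repeated selection would collapse error variability. Single-letter
# function words (a, e, o, u, y) are deliberately NOT listed: they carry
# homophone errors (a/ha, e/he).
skip_list:
  - el
  - la
  - los
  - las
  - un
  - una
  - unos
  - unas
  - lo
  - al
  - del
  - este
  - esta
  - estos
  - estas
  - ese
  - esa
  - esos
  - esas
  - aquel
  - aquella
  - aquellos
  - aquellas
  - mi
  - mis
  - tu
  - tus
  - su
  - sus
  - nuestro
  - nuestra
  - nuestros
  - nuestras
  - ante
  - bajo
  - con
  - contra
  - de
  - desde
  - durante
  - en
  - entre
  - hacia
  - hasta
  - mediante
  - para
  - por
  - según
  - sin
  - sobre
  - tras
  - que
  - se
  - no
  - si
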