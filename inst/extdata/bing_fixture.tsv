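# binary fixture lexicon (Bing schema): token<TAB>positive|negative
pos01	positive
pos02	positive
pos03	positive
pos04	positive
pos05	positive
pos06	positive
pos07	positive
pos08	positive
pos09	positive
pos10	positive
pos11	positive
pos12	positive
estable	positive
tranquilo	positive
contento	positive
feliz	positive
animado	positive
comodo	positive
neg01	negative
neg02	negative
neg03	negative
neg04	negative
neg05	negative
neg06	negative
neg07	negative
neg08	negative
neg09	negative
neg10	negative
neg11	negative
neg12	negative
inquieto	negative
agitado	negative
dolorido	negative
triste	negative
nervioso	negative
incomodo	negative
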