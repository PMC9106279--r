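# valence fixture lexicon (Afinn schema): token<TAB>score in [-5,5]\{0}
pos01	1
pos02	2
pos03	3
pos04	4
pos05	1
pos06	2
pos07	3
pos08	4
pos09	1
pos10	2
pos11	3
pos12	5
neg01	-1
neg02	-2
neg03	-3
neg04	-4
neg05	-1
neg06	-2
neg07	-3
neg08	-4
neg09	-1
neg10	-2
neg11	-3
neg12	-5
estable	1
tranquilo	2
contento	2
feliz	3
animado	3
comodo	2
inquieto	-2
agitado	-2
dolorido	-3
triste	-2
nervioso	-2
incomodo	-2
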