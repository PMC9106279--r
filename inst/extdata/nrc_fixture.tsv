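# emotion fixture lexicon (NRC schema): token<TAB>category
pos01	positive
pos01	joy
pos02	positive
pos02	trust
pos03	positive
pos03	anticipation
pos04	positive
pos04	surprise
pos05	positive
pos05	joy
pos06	positive
pos06	trust
pos07	positive
pos07	anticipation
pos08	positive
pos08	surprise
pos09	positive
pos09	joy
pos10	positive
pos10	trust
pos11	positive
pos11	anticipation
pos12	positive
pos12	surprise
estable	positive
estable	joy
tranquilo	positive
tranquilo	trust
contento	positive
contento	anticipation
feliz	positive
feliz	surprise
animado	positive
animado	joy
comodo	positive
comodo	trust
neg01	negative
neg01	sadness
neg02	negative
neg02	fear
neg03	negative
neg03	anger
neg04	negative
neg04	disgust
neg05	negative
neg05	sadness
neg06	negative
neg06	fear
neg07	negative
neg07	anger
neg08	negative
neg08	disgust
neg09	negative
neg09	sadness
neg10	negative
neg10	fear
neg11	negative
neg11	anger
neg12	negative
neg12	disgust
inquieto	negative
inquieto	sadness
agitado	negative
agitado	fear
dolorido	negative
dolorido	anger
triste	negative
triste	disgust
nervioso	negative
nervioso	sadness
incomodo	negative
incomodo	fear
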