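# lemma table: surface<TAB>lemma
corriendo	correr
estables	estable
tranquila	tranquilo
tristes	triste
agitada	agitado
contenta	contento
fiebres	fiebre
dolores	dolor
comoda	comodo
nerviosa	nervioso
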