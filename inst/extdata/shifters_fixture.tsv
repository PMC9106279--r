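# valence-shifter fixture lexicon: token<TAB>negator|amplifier|deamplifier
no	negator
nunca	negator
tampoco	negator
muy	amplifier
mucho	amplifier
bastante	amplifier
poco	deamplifier
apenas	deamplifier
algo	deamplifier
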