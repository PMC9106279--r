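el
la
los
las
de
del
y
en
se
con
a
por
para
un
una
es
su
al
que
lo
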