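parent	child
D	Da
D	Db
Ea	Ea1-2
Ea	Ea3-4
Eb	Eb1-4
Eb	Eb5-8
E	Ea
E	Eb
S	Sa
S	Sb
R.decollata	A
R.decollata	B
R.decollata	C
R.decollata	D
R.decollata	E
R.decollata	F
R.saharica	S
Rumina	R.decollata
Rumina	R.saharica
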