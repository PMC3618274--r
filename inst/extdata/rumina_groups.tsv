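id	group
hapA	A
hapB	B
hapC	C
hapDa	Da
hapDb	Db
hapEa12	Ea1-2
hapEa34	Ea3-4
hapEb14	Eb1-4
hapEb58	Eb5-8
hapF	F
hapSa	Sa
hapSb	Sb
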