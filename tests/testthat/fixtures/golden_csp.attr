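attribute: csp
match mode: 1-to-1
recipient: residues
	:10	0.125
	:11	0.0314159
	:12	0.0000125
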