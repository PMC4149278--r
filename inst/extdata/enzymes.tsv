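name	site	cut_offset
BsrI	ACTGG	1
EcoRI	GAATTC	-5
BamHI	GGATCC	-5
HindIII	AAGCTT	-5
DraI	TTTAAA	-3
MboI	GATC	-4
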