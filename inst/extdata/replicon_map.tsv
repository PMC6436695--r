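accession	replicon	cds
CP004015.1	chromosome	3672
CP004016.1	pRtrCIAT899a	212
CP004017.1	pRtrCIAT899b	500
CP004018.1	pRtrCIAT899c	1905
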