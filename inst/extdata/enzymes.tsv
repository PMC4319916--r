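name	site	offset
BsrBI	CCGCTC	3
EcoRI	GAATTC	NA
HindIII	AAGCTT	NA
BamHI	GGATCC	NA
TaqI	TCGA	NA
DdeI	CTNAG	NA
HinfI	GANTC	NA
BsrBI_printed	TCCGCTCC	4
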