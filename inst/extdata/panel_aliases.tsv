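C17orf70	FAAP100
KIAA0146	SPIDR
MMS4L	EME1
KIAA1794	FANCI
FANCD1	BRCA2
H2AFX	H2AX
C19orf40	FAAP24
SHFM1	SEM1
MRE11A	MRE11
FAM175A	ABRAXAS1
OBFC2B	NABP2
C7orf49	MRI
C9orf142	PAXX
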