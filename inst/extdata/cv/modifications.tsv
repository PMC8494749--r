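# synthetic snapshot: protein modifications (UNIMOD subset)
UNIMOD:35	Oxidation	UNIMOD
UNIMOD:4	Carbamidomethyl	UNIMOD
UNIMOD:21	Phospho	UNIMOD
UNIMOD:1	Acetyl	UNIMOD
UNIMOD:7	Deamidated	UNIMOD
UNIMOD:36	Dimethyl	UNIMOD
UNIMOD:34	Methyl	UNIMOD
UNIMOD:121	GG	UNIMOD
UNIMOD:737	TMT6plex	UNIMOD
UNIMOD:2016	TMTpro	UNIMOD
UNIMOD:188	Label:13C(6)	UNIMOD
UNIMOD:259	Label:13C(6)15N(2)	UNIMOD
UNIMOD:267	Label:13C(6)15N(4)	UNIMOD
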