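# synthetic snapshot: cell lines (EFO subset)
EFO:0001185	HeLa	EFO
EFO:0001184	HEK293	EFO
EFO:0002067	K562	EFO
EFO:0001098	Jurkat	EFO
EFO:0001086	A549	EFO
EFO:0001203	MCF-7	EFO
EFO:0002847	U2OS	EFO
EFO:0001232	SH-SY5Y	EFO
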