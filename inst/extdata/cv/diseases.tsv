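# synthetic snapshot: diseases and phenotype states (EFO/MONDO/PATO subset)
PATO:0000461	normal	PATO
EFO:0000311	cancer	EFO
EFO:0000305	breast carcinoma	EFO
EFO:0001061	colorectal cancer	EFO
EFO:0000182	hepatocellular carcinoma	EFO
EFO:0000571	lung adenocarcinoma	EFO
EFO:0000400	diabetes mellitus	EFO
EFO:0000249	Alzheimer disease	EFO
EFO:0002508	Parkinson disease	EFO
EFO:0000685	rheumatoid arthritis	EFO
MONDO:0004992	cancer or benign tumor	MONDO
MONDO:0005575	colorectal carcinoma	MONDO
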