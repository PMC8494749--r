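# synthetic snapshot: mass spectrometers (PSI-MS subset)
MS:1001911	Q Exactive	MS
MS:1002634	Q Exactive Plus	MS
MS:1002523	Q Exactive HF	MS
MS:1002416	Orbitrap Fusion	MS
MS:1002732	Orbitrap Fusion Lumos	MS
MS:1003028	Orbitrap Exploris 480	MS
MS:1000449	LTQ Orbitrap	MS
MS:1001742	LTQ Orbitrap Velos	MS
MS:1002533	TripleTOF 6600	MS
MS:1002996	timsTOF Pro	MS
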