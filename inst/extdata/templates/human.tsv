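# human-dataset template: disease is mandatory, ancestry recommended,
# organism fixed, control samples expected to carry the disease value "normal"
name	human
rule	H1	require	ERROR	characteristics[disease]
rule	H2	require	WARNING	characteristics[ancestry]
rule	H3	value_equals	ERROR	characteristics[organism]	Homo sapiens
rule	H4	expect_value	INFO	characteristics[disease]	normal
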