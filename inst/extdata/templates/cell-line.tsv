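# cell-line template: the cell line is recommended metadata, enforced as an
# error when this template is requested explicitly
name	cell line
rule	C1	require	ERROR_IF_EXPLICIT	characteristics[cell line]
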