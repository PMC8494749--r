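# synthetic snapshot: cleavage agents (PSI-MS subset)
MS:1001251	Trypsin	MS
MS:1001313	Trypsin/P	MS
MS:1001309	Lys-C	MS
MS:1001303	Arg-C	MS
MS:1001304	Asp-N	MS
MS:1001306	Chymotrypsin	MS
MS:1001917	Glu-C	MS
MS:1001955	no cleavage	MS
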