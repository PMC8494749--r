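# synthetic snapshot: organism parts (UBERON subset)
UBERON:0002107	liver	UBERON
UBERON:0000955	brain	UBERON
UBERON:0002048	lung	UBERON
UBERON:0000948	heart	UBERON
UBERON:0002113	kidney	UBERON
UBERON:0000178	blood	UBERON
UBERON:0002371	bone marrow	UBERON
UBERON:0001155	colon	UBERON
UBERON:0002106	spleen	UBERON
UBERON:0002367	prostate gland	UBERON
UBERON:0000310	breast	UBERON
UBERON:0001264	pancreas	UBERON
UBERON:0002097	skin of body	UBERON
UBERON:0000945	stomach	UBERON
UBERON:0000473	testis	UBERON
UBERON:0000992	ovary	UBERON
UBERON:0001134	skeletal muscle tissue	UBERON
UBERON:0000479	tissue	UBERON
UBERON:0000468	whole organism	UBERON
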