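pathway	gene
RAS_MAPK_signalling	KRAS
RAS_MAPK_signalling	NRAS
RAS_MAPK_signalling	HRAS
RAS_MAPK_signalling	EGFR
RAS_MAPK_signalling	ERBB2
RAS_MAPK_signalling	MAP3K11
RAS_MAPK_signalling	GENE001
RAS_MAPK_signalling	GENE002
DNA_damage_repair	BRCA1
DNA_damage_repair	BRCA2
DNA_damage_repair	PALB2
DNA_damage_repair	POLQ
DNA_damage_repair	POLE
DNA_damage_repair	ATM
DNA_damage_repair	ATR
DNA_damage_repair	GENE003
TGFb_signalling	SMAD4
TGFb_signalling	TGFBR1
TGFb_signalling	TGFBR2
TGFb_signalling	GENE004
Chromatin_modification	KMT2D
Chromatin_modification	PBRM1
Chromatin_modification	ARID5B
Chromatin_modification	GENE005
WNT_signalling	RNF43
WNT_signalling	WNT5A
WNT_signalling	GENE006
Cell_cycle	CDKN2A
Cell_cycle	TP53
Cell_cycle	GENE007
Axon_guidance	SRGAP3
Axon_guidance	ANK3
Axon_guidance	TNC
Axon_guidance	GENE008
Housekeeping	GENE009
Housekeeping	GENE010
Housekeeping	GENE011
Housekeeping	GENE012
Housekeeping	GENE013
Housekeeping	GENE014
Housekeeping	GENE015
Housekeeping	GENE016
Housekeeping	GENE017
Housekeeping	GENE018
Housekeeping	GENE019
Housekeeping	GENE020
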