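gene	class	therapy
KRAS	PDAC-driver
TP53	PDAC-driver
SMAD4	PDAC-driver
CDKN2A	PDAC-driver
NRAS	RAS-family
HRAS	RAS-family
BRCA1	DDR-biomarker	PARPi/platinum
BRCA2	DDR-biomarker	PARPi/platinum
PALB2	DDR-biomarker	PARPi/platinum
POLQ	DDR-pathway
POLE	DDR-pathway
ATM	DDR-pathway
ATR	DDR-pathway
MTOR	alt-driver
ERBB2	alt-driver	anti-ERBB2
EGFR	alt-driver
PBRM1	alt-driver
KMT2D	alt-driver
RNF43	alt-driver
IDH1	alt-driver	IDH-inhibitor
IDH2	alt-driver	IDH-inhibitor
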