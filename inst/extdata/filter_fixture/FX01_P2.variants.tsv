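chrom	pos	ref	alt	sample_id	ref_fwd	ref_rev	alt_fwd	alt_rev	mean_alt_bq	cosmic_id	dbsnp_id	exonic_function	af_1000g	af_gnomad	af_hapmap	gene	driver_class	biomarker	context
chr1	1000	C	T	FX01_P2	420	410	45	40	35	COSV000001	.	nonsynonymous	.	.	.	KRAS	.	.	ACA
chr3	3000	G	A	FX01_P2	460	470	22	25	35	.	.	stopgain	.	.	.	BRCA2	.	.	AGA
chr4	4000	T	A	FX01_P2	480	480	15	12	33	.	.	nonsynonymous	.	.	.	SMAD4	.	.	ATA
chr10	10000	A	C	FX01_P2	430	420	18	22	36	.	.	nonsynonymous	.	.	.	GENE001	.	.	AAA
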