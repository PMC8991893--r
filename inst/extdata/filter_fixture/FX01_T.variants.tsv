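chrom	pos	ref	alt	sample_id	ref_fwd	ref_rev	alt_fwd	alt_rev	mean_alt_bq	cosmic_id	dbsnp_id	exonic_function	af_1000g	af_gnomad	af_hapmap	gene	driver_class	biomarker	context
chr1	1000	C	T	FX01_T	20	20	6	5	35	COSV000001	.	nonsynonymous	.	.	.	KRAS	.	.	ACA
chr3	3000	G	A	FX01_T	25	22	4	4	34	.	.	stopgain	.	.	.	BRCA2	.	.	AGA
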