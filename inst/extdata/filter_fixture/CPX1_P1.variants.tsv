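chrom	pos	ref	alt	sample_id	ref_fwd	ref_rev	alt_fwd	alt_rev	mean_alt_bq	cosmic_id	dbsnp_id	exonic_function	af_1000g	af_gnomad	af_hapmap	gene	driver_class	biomarker	context
chr9	9000	C	T	CPX1_P1	480	490	2	1	34	.	.	nonsynonymous	.	.	.	GENE001	.	.	ACA
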