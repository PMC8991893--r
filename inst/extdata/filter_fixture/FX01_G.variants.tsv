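chrom	pos	ref	alt	sample_id	ref_fwd	ref_rev	alt_fwd	alt_rev	mean_alt_bq	cosmic_id	dbsnp_id	exonic_function	af_1000g	af_gnomad	af_hapmap	gene	driver_class	biomarker	context
chr1	1000	C	T	FX01_G	50	50	0	0	.	.	.	nonsynonymous	.	.	.	GENE001	.	.	ACA
chr2	2000	A	G	FX01_G	50	50	0	0	.	.	.	nonsynonymous	.	.	.	GENE001	.	.	AAA
chr3	3000	G	A	FX01_G	50	50	0	0	.	.	.	nonsynonymous	.	.	.	GENE001	.	.	AGA
chr4	4000	T	A	FX01_G	50	50	0	0	.	.	.	nonsynonymous	.	.	.	GENE001	.	.	ATA
chr5	5000	C	A	FX01_G	50	50	0	0	.	.	.	nonsynonymous	.	.	.	GENE001	.	.	ACA
chr6	6000	C	T	FX01_G	50	50	0	0	.	.	.	nonsynonymous	.	.	.	GENE001	.	.	ACA
chr7	7000	C	G	FX01_G	50	50	0	0	.	.	.	nonsynonymous	.	.	.	GENE001	.	.	ACA
chr8	8000	A	T	FX01_G	47	48	3	2	35	.	.	nonsynonymous	.	.	.	GENE001	.	.	AAA
chr9	9000	C	T	FX01_G	50	50	0	0	.	.	.	nonsynonymous	.	.	.	GENE001	.	.	ACA
chr10	10000	A	T	FX01_G	50	50	0	0	.	.	.	nonsynonymous	.	.	.	GENE001	.	.	AAA
chr11	150	C	T	FX01_G	50	50	0	0	.	.	.	nonsynonymous	.	.	.	GENE001	.	.	ACA
chr12	12000	C	T	FX01_G	50	50	0	0	.	.	.	nonsynonymous	.	.	.	GENE001	.	.	ACA
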