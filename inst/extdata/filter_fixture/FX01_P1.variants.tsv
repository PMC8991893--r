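chrom	pos	ref	alt	sample_id	ref_fwd	ref_rev	alt_fwd	alt_rev	mean_alt_bq	cosmic_id	dbsnp_id	exonic_function	af_1000g	af_gnomad	af_hapmap	gene	driver_class	biomarker	context
chr1	1000	C	T	FX01_P1	400	400	50	50	36	COSV000001	.	nonsynonymous	.	.	.	KRAS	.	.	ACA
chr2	2000	A	G	FX01_P1	450	450	30	30	35	.	.	nonsynonymous	.	.	.	TP53	.	.	AAA
chr3	3000	G	A	FX01_P1	470	480	25	20	34	.	.	stopgain	.	.	.	BRCA2	.	.	AGA
chr5	5000	C	A	FX01_P1	400	400	40	40	36	.	rs0000111	nonsynonymous	.	0.001	.	GENE001	.	.	ACA
chr6	6000	C	T	FX01_P1	400	400	40	40	36	.	.	synonymous	.	.	.	GENE001	.	.	ACA
chr7	7000	C	G	FX01_P1	400	400	40	40	24.5	.	.	nonsynonymous	.	.	.	GENE001	.	.	ACA
chr8	8000	A	T	FX01_P1	400	400	40	40	36	.	.	nonsynonymous	.	.	.	GENE001	.	.	AAA
chr9	9000	C	T	FX01_P1	400	400	40	40	36	.	.	nonsynonymous	.	.	.	GENE001	.	.	ACA
chr10	10000	A	T	FX01_P1	420	420	20	20	36	.	.	nonsynonymous	.	.	.	GENE001	.	.	AAA
chr11	150	C	T	FX01_P1	400	400	40	40	36	.	.	nonsynonymous	.	.	.	GENE001	.	.	ACA
chr12	12000	C	T	FX01_P1	400	400	30	1	36	.	.	nonsynonymous	.	.	.	GENE001	.	.	ACA
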