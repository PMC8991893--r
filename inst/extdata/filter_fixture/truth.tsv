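key	class	designed_stage
chr1:1000:C>T	true_somatic	NA
chr2:2000:A>G	true_somatic	NA
chr3:3000:G>A	true_somatic	NA
chr4:4000:T>A	true_somatic	NA
chr5:5000:C>A	dbsnp_only	dbsnp_only
chr6:6000:C>T	synonymous	exonic_function
chr7:7000:C>G	low_bq	base_quality
chr8:8000:A>T	germline_leak	germline
chr9:9000:C>T	cp_shared	cp_control
chr10:10000:A>T	multiallelic	multiallelic
chr10:10000:A>C	multiallelic	multiallelic
chr11:150:C>T	blacklist	blacklist
chr12:12000:C>T	strand_bias	strand_bias
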