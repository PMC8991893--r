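patient_id	sample_id	sample_class	timepoint_label	day
FX01	FX01_T	tumour	T	0
FX01	FX01_G	germline	G	0
FX01	FX01_P1	plasma	P1	10
FX01	FX01_P2	plasma	P2	100
CPX1	CPX1_P1	cp_control	P1	0
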