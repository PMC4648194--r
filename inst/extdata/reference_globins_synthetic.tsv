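id	family	type	thb_class	f8	e7	b10	cd1
ref_fhb_syn	M	fHb	NA	88	62	30	42
ref_sdgb_syn	M	SDgb	NA	88	62	30	42
ref_gcs_syn	S	GCS	NA	88	62	30	42
ref_protoglobin_syn	S	protoglobin	NA	143	117	85	97
ref_ssdgb_syn	S	SSDgb	NA	88	62	30	42
ref_thb1_syn	T	tHb1	1	76	52	24	36
ref_thb2_syn	T	tHb2	2	76	52	24	36
ref_thb3_syn	T	tHb3	3	76	52	24	36
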