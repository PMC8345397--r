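group	n	age_mean	age_sd	male_n	female_n	multiple_crc_n	fam_history_crc_n	expected_mf_ratio	expected_multiple_crc_pct
fcrc	417	48.72	12.40	235	186	32	213	1.26	7.67
sp	80	52.29	12.60	53	27	9	30	1.96	11.25
sporadic_crc	1077	66.87	10.88	702	375	NA	132	1.87	NA
control	1642	62.40	10.25	835	807	NA	84	1.03	NA
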