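feature	pos_label	neg_label	high_pos	high_neg	low_pos	low_neg	expected_chi2_p
gender	male	female	91	67	76	51	0.7018
deceased_status	alive	deceased	144	13	116	10	0.9162
age_at_dx	lt50	ge50	94	64	94	33	0.0101
hnpcc_criteria	amsterdam	bethesda	24	134	17	110	0.6662
fam_history_crc	yes	no	90	64	53	71	0.0092
multiple_primary_crc	yes	no	19	139	6	121	0.0303
multiple_primary_any	yes	no	28	130	14	113	0.1129
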