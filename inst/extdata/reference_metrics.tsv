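subcategory	gold_n	gold_pct	precision	recall	f_score
relatives_unknown_involvement	128	69.6	0.52	0.97	0.68
lacking_capacity	119	64.7	0.67	0.99	0.8
surrogate_identified	53	28.8	0.94	0.75	0.83
advance_directives_available	33	17.9	0.94	0.92	0.93
community_connection	20	10.9	0.85	1	0.92
married	11	6	0.64	1	0.78
unmarried	7	3.8	1	0.64	0.78
living_alone	7	3.8	0.86	0.75	0.8
living_with_others	7	3.8	1	0.64	0.78
surrogate_unidentified	7	3.8	0.29	0.67	0.4
partnered	6	3.3	1	0.86	0.92
transitionally_situated	5	2.7	1	1	1
religious_connections	3	1.6	0.67	1	0.8
palliative_care	2	1.1	1	1	1
hospice	1	0.5	1	1	1
caregiver_support	NA	NA	NA	NA	NA
advance_directives_unavailable	NA	NA	NA	NA	NA
overall	184	100	0.83	0.88	0.83
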