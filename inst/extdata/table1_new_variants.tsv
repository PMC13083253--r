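variant_id	gene	mac_case_disc	maf_case_disc	mac_control_disc	maf_control_disc	or_disc	p_discovery	mac_case_rep	maf_case_rep	mac_control_rep	maf_control_rep	or_rep	p_replication	p_meta	n_cases_disc	n_controls_disc	n_cases_rep	n_controls_rep
9:133154147:C:A	GBGT1	14	5.34e-4	3	2.15e-5	26.9	1.68e-10	1	1.05e-4	0	0	44.7	1.34e-2	1.99e-11	13138	69775	4781	130928
7:44206388:A:G	YKT6	48	1.83e-3	91	6.52e-4	2.84	9.08e-8	15	1.57e-3	164	6.26e-4	2.54	4.15e-3	1.50e-9	13138	69775	4781	130928
1:223762207:A:G	CAPN2	12	4.57e-4	3	2.15e-5	25.3	3.66e-9	1	1.05e-4	3	1.15e-5	5.11	1.69e-1	1.18e-8	13138	69775	4781	130928
3:184057041:A:G	HTR3C	39	1.48e-3	70	5.05e-4	3.41	1.87e-8	6	6.28e-4	97	3.71e-4	2.18	9.15e-2	1.71e-8	13138	69775	4781	130928
12:122547457:T:A	KNTC1	9	3.43e-4	2	1.43e-5	27.7	1.07e-7	1	1.05e-4	2	7.64e-6	12.2	4.67e-2	2.96e-8	13138	69775	4781	130928
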