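variable	mean_a	sd_a	n_a	mean_b	sd_b	n_b	p_printed
Age_years	49.11	9.68	33	52.50	9.66	24	0.194
Sex_female	20	NA	33	14	NA	24	0.970
Education_years	13.03	3.53	33	11.88	3.30	24	0.215
BMI_kg_m2	25.42	2.83	33	24.19	3.33	24	0.135
Systolic_BP_mmHg	122.78	11.51	33	122.92	15.66	24	0.969
Diastolic_BP_mmHg	77.17	11.13	33	75.42	7.99	24	0.513
Total_cholesterol_mmol_l	5.36	0.97	33	5.18	0.91	24	0.478
HDL_cholesterol_mmol_l	1.52	0.46	33	1.68	0.54	24	0.230
LDL_cholesterol_mmol_l	2.79	2.91	33	2.91	0.67	24	0.844
Cr_umol_L	68.21	14.82	33	68.79	13.46	24	0.878
FPG_mmol_L	8.48	3.22	33	5.20	0.40	24	0.001
PG2h_mmol_l	12.31	5.37	33	5.71	1.06	24	0.001
Fasting_insulin_uU_ml	12.86	9.62	33	10.44	6.02	24	0.281
Fasting_C_peptide_ng_ml	2.38	1.09	33	1.97	0.68	24	0.109
HbA1c_pct	7.30	1.97	33	5.60	0.25	24	0.001
HOMA_beta_pct	64.06	50.11	33	109.37	48.43	24	0.001
HOMA_IR	2.02	1.30	33	1.25	0.76	24	0.012
MoCA	26.32	2.42	33	24.38	3.99	24	0.058
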