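set_name	E2100	E2197	GSE25055	GSE25065	METABRIC_DISC	METABRIC_VAL	TCGA	reported_combined_p
V$HIF1_Q5	0.428	0.002	0.002	0.103	0.006	0.041	0.003	4.98e-09
V$HIF1_Q3	0.536	0.000	0.000	0.021	0.022	0.067	0.011	1.08e-08
KTGGYRSGAA_UNKNOWN	0.810	0.000	0.024	0.031	0.034	0.008	0.030	1.86e-07
V$E2F1_Q6	0.777	0.000	0.000	0.008	0.111	0.043	0.040	2.16e-07
V$GNCF_01	0.000	0.000	0.016	0.124	0.020	0.047	0.338	4.34e-07
V$HMGIY_Q6	0.006	0.010	0.028	0.051	0.057	0.028	0.029	9.29e-07
MCAATNNNNNGCG_UNKNOWN	0.543	0.004	0.164	0.092	0.039	0.125	0.000	3.40e-06
V$E2F_01	0.556	0.000	0.036	0.030	0.175	0.056	0.023	3.78e-06
TTCNRGNNNNTTC_V$HSF_Q6	0.175	0.008	0.022	0.004	0.070	0.089	0.085	4.11e-06
CTGRYYYNATT_UNKNOWN	0.008	0.056	0.055	0.061	0.024	0.066	0.032	1.02e-05
V$MYCMAX_02	0.620	0.000	0.020	0.288	0.176	0.111	0.036	2.37e-05
V$MYC_Q2	0.402	0.014	0.004	0.099	0.116	0.175	0.052	3.61e-05
V$TAXCREB_02	0.570	0.032	0.037	0.160	0.047	0.032	0.051	5.53e-05
CATTGTYY_V$SOX9_B1	0.281	0.030	0.080	0.017	0.045	0.084	0.118	6.33e-05
V$E2F_Q3	0.606	0.002	0.029	0.059	0.249	0.167	0.071	7.11e-05
V$AP1_Q4	0.428	0.008	0.185	0.471	0.052	0.018	0.063	9.65e-05
MYAATNNNNNNNGGC_UNKNOWN	0.265	0.021	0.106	0.131	0.079	0.100	0.121	2.59e-04
V$NFY_Q6	0.800	0.010	0.029	0.157	0.091	0.133	0.168	2.71e-04
V$AP1_01	0.333	0.019	0.113	0.358	0.056	0.057	0.180	3.90e-04
V$USF_C	0.756	0.008	0.152	0.252	0.275	0.095	0.014	5.34e-04
CCAWYNNGAAR_UNKNOWN	0.713	0.028	0.048	0.189	0.454	0.119	0.003	6.90e-04
V$NFKAPPAB_01	0.054	0.022	0.529	0.634	0.017	0.050	0.164	7.14e-04
TGASTMAGC_V$NFE2_01	0.702	0.055	0.061	0.151	0.052	0.028	0.318	7.44e-04
V$MYCMAX_01	0.823	0.015	0.187	0.413	0.246	0.069	0.008	8.60e-04
TTGCWCAAY_V$CEBPB_02	0.420	0.010	0.097	0.181	0.120	0.293	0.180	8.64e-04
V$TCF11MAFG_01	0.586	0.138	0.053	0.054	0.066	0.050	0.179	9.81e-04
V$BACH2_01	0.230	0.035	0.173	0.243	0.097	0.164	0.120	0.001
V$ZIC3_01	0.050	0.079	0.080	0.325	0.096	0.237	0.157	0.002
RAAGNYNNCTTY_UNKNOWN	0.657	0.088	0.067	0.205	0.082	0.090	0.326	0.004
V$TCF1P_Q6	0.148	0.042	0.067	0.332	0.228	0.305	0.169	0.004
V$AP1FJ_Q2	0.202	0.065	0.256	0.385	0.158	0.148	0.132	0.006
V$AP1_Q2	0.253	0.146	0.116	0.376	0.158	0.141	0.088	0.006
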