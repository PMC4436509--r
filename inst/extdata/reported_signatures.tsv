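set_name	n_genes	n_cohorts	genes
CATTGTYY_V$SOX9_B1	21	7	ANKRD11 BCL11A CDK8 CLIC4 EHBP1 FEN1 FGF9 ILF2 MID1 NASP NDRG2 NXN RBMS1 S100A1 SEPHS1 SFRP1 SLC6A9 TLE1 TRIM2 VLDLR YEATS2
V$HIF1_Q3	18	7	ATP1B3 BCL11A CA9 E2F3 EN1 ENO1 EPHB3 GPM6B IGF2BP3 KIAA0664 KLF11 LRP8 NFIL3 NPR3 ST6GAL1 VEGFA YBX1 YEATS2
V$HMGIY_Q6	16	7	ANKRD11 ATP1B3 BCL11A CXCL10 DLL3 DONSON EN1 FAM98A LMO4 MIA NDRG2 NMU PPP2R3A PTPN22 ST8SIA1 TFAP2C
V$HIF1_Q5	13	7	BCL11A CA9 E2F3 EN1 EPHB3 GPM6B IGF2BP3 KLF11 LRP8 NT5DC2 PIM1 VEGFA YBX1
V$MYC_Q2	10	7	CSDA FOSL1 FXYD6 IL15RA IVNS1ABP LRP8 PABPC4 REXO2 TAGLN2 YBX1
TTCNRGNNNNTTC_V$HSF_Q6	8	7	CRYAB E2F3 H2AFY2 LRP8 SLC15A2 TBPL1 TFCP2L1 VEGFA
MYAATNNNNNNNGGC_UNKNOWN	7	7	AMD1 BBOX1 CDC20 KRT9 PTK7 TLE1 TLE4
TTGCWCAAY_V$CEBPB_02	7	7	CEBPB CLDN10 KRT23 SOX10 SPIB SRPK1 SYNCRIP
CTGRYYYNATT_UNKNOWN	6	7	CDC42EP1 COL9A1 CRYAB DKK1 SMOX SOX10
V$E2F1_Q6	36	6	ARHGAP11A ATAD5 CDC25A CDK1 DMD DNMT1 E2F3 EFNA5 EHBP1 EPHB1 EZH2 FANCG FBXO5 GAPDH GINS3 GMNN GPRC5B H2AFZ KLF5 MCM3 MCM4 MCM6 MCM7 MYC NASP NCL NUP62 PIM1 POLD1 PRPS2 RANBP1 RBL1 RRM2 SYNCRIP TYRO3 WDR62
V$E2F_Q3	28	6	ARHGAP11A CDC25A CDC45 CDK1 DMD DNMT1 DPYSL2 E2F3 EPHB1 EZH2 FBXO5 GMNN KIF15 KLF5 MCM3 MCM4 MCM6 MCM7 NASP NPR3 NUP153 PIM1 PLK4 POLA2 RANBP1 TCP1 TIPIN USP1
V$NFY_Q6	18	6	ACTL6A BUB1 CDK1 CENPF CKS2 GART LRP8 MYO1E NEK2 PNOC PRR11 PTCH1 SFRP1 TLE4 TOP2A TTK UGP2 ZBTB5
KTGGYRSGAA_UNKNOWN	12	6	EZH2 MCM3 MCM6 MCM7 MYC PIM1 POLD1 RANBP1 RFC4 SYNCRIP TUBA4A YARS
V$GNCF_01	10	6	ABTB2 AMD1 BCL11A BCL11B FGF9 ITGB8 MALL NFIB NFIL3 RASAL1
V$E2F_01	9	6	AMD1 DNMT1 E2F3 MCM3 MCM4 MYC NASP RANBP1 SMC4
MCAATNNNNNGCG_UNKNOWN	8	6	AMD1 CDCA3 EPHB1 PIGA PPP2R5D SH3BGRL3 SUV39H1 ZFAND5
V$TAXCREB_02	2	6	BCL11A CRLF1
V$NFKAPPAB_01	26	5	CBX2 CCL5 CD40 CD70 CD83 CDK6 CXCL10 CXCL11 CXCL16 IL27RA ITGB4 LIX1L LTA MSN NFKB2 NFKBIB ORAI1 RBMS1 RELB SMOC1 SOX10 TNFRSF9 TRIM47 UBD WNT10A ZBTB5
V$AP1_Q4	25	5	ASS1 CA9 COL27A1 CORO1C EDN1 EPHA2 FGF11 GJB3 GPR3 IRAK1 KCNN4 KIAA0664 LAMB3 LAMC2 MAP2 MMP7 PIM2 REXO2 SLC4A11 STK40 TAGLN2 UBE2C UCHL3 USP13 XIRP1
V$MYCMAX_01	22	5	ATAD3A CSK EIF2C2 ESRRA GCSH GPM6B HMGA1 IVNS1ABP KCNN4 KIAA0664 LRP8 ODC1 PABPC1 PPRC1 PRDX4 RANBP1 REXO2 SLC6A15 SYNCRIP TIMM8A TUBA4A YEATS2
V$AP1_01	20	5	AQP5 CA9 CALB2 DMD ENO1 EPHA2 FGF9 FOSL1 GSTP1 IRAK1 LY6D MAP2 MMP7 PIM1 REXO2 S100A2 SERPINB5 TAGLN2 TINAGL1 TUBA4A
V$TCF11MAFG_01	18	5	CDC45 DYNC1I1 E2F3 ENO1 FGF9 FOSL1 IRX4 JOSD1 LMO4 NUDT11 PLS3 PPARGC1A PTCH1 REXO2 SEL1L3 SERPINB5 SOBP UCHL1
TGASTMAGC_V$NFE2_01	12	5	ANGPTL4 ASS1 CA9 CALB2 E2F3 FOSL1 GSTP1 MYO10 PLS3 S100A2 SERPINB5 TINAGL1
CCAWYNNGAAR_UNKNOWN	10	5	AKR1B1 ARL4C CDC45 CKS1B DMD FAM49A RBMS1 TBX19 UQCRH YBX1
V$MYCMAX_02	18	4	CALB2 DZIP1 EN1 FBL FRMD4A HDGF HIF1A IVNS1ABP KIAA0664 NOTCH1 PABPC4 PPRC1 PTCH1 PTK7 SOX10 SYNCRIP TNFRSF21 TYRO3
V$USF_C	12	4	ASS1 BATF3 EIF2C2 ETV4 FBL IVNS1ABP LRP8 PABPC4 SLC6A15 ST6GAL1 TNFRSF21 YBX1
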