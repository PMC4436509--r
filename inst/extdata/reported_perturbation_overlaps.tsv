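perturbation	cgp_set	signature	genes_found
Ras inhibitor Salirasib	BLUM_RESPONSE_TO_SALIRASIB_DN	V$E2F_01	DNMT1 MCM3 NASP RANBP1 SMC4
Ras inhibitor Salirasib	BLUM_RESPONSE_TO_SALIRASIB_DN	V$E2F_Q3	CDC25A CDC45 CDK1 DNMT1 EZH2 FBXO5 GMNN KIF15 MCM3 MCM6 NASP PLK4 POLA2 RANBP1 USP1
Ras inhibitor Salirasib	BLUM_RESPONSE_TO_SALIRASIB_DN	KTGGYRSGAA_UNKNOWN	EZH2 MCM3 MCM6 POLD1 RANBP1 RFC4 SYNCRIP
EGFR inhibitor CL-387785	KOBAYASHI_EGFR_SIGNALING_24HR_DN	V$E2F_Q3	CDC25A CDC45 CDK1 EZH2 GMNN KIF15 MCM3 MCM4 MCM6 MCM7 PLK4 POLA2 RANBP1 TIPIN USP1
Aminopeptidase inhibitor Tosedostat (CHR-2797)	KRIGE_RESPONSE_TO_TOSEDOSTAT_24HR_DN	V$E2F_01	AMD1 MYC NASP RANBP1 SMC4
SB216763 inhibitor of GSK3B	WANG_RESPONSE_TO_GSK3_INHIBITOR_SB216763_DN	V$E2F_01	MCM3 MCM4 MYC NASP RANBP1
SB216763 inhibitor of GSK3B	WANG_RESPONSE_TO_GSK3_INHIBITOR_SB216763_DN	KTGGYRSGAA_UNKNOWN	MCM3 MCM6 MCM7 MYC PIM1 RANBP1 TUBA4A
Knockout TLX	ZHANG_TLX_TARGETS_60HR_DN	V$E2F_01	AMD1 DNMT1 MCM3 MCM4 NASP SMC4
Knockout TLX	ZHANG_TLX_TARGETS_60HR_DN	KTGGYRSGAA_UNKNOWN	EZH2 MCM3 MCM6 MCM7 POLD1 RFC4 SYNCRIP
Knockout BMP2	LEE_BMP2_TARGETS_DN	V$E2F_Q3	CDC25A CDC45 DNMT1 E2F3 EZH2 GMNN KLF5 MCM3 MCM4 MCM6 MCM7 NASP NUP153 PLK4 RANBP1 TIPIN USP1
Knockout BMP2	LEE_BMP2_TARGETS_DN	V$E2F_01	AMD1 DNMT1 E2F3 MCM3 MCM4 NASP RANBP1
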