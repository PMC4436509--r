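cohort	n_tn	n_er	tn_pattern	er_pattern	platform
E2100	49	65	NNN	PXN	Illumina DASL (quantile)
E2197	191	382	NNN	PXN	Illumina DASL (cubic spline)
GSE25055	114	165	NNN	PXN	Affymetrix U133A
GSE25065	64	123	NNN	PXN	Affymetrix U133A
METABRIC_DISC	69	344	Nn1	PX1	Illumina V4
METABRIC_VAL	52	184	Nn1	PX1	Illumina V4
TCGA	58	228	NNN	PXN	RNA-Seq V2 RSEM
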