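gene	motif	start	strand
spB_TF_L1_02	MOTIF_bHLH	237	+
spB_TF_L1_03	MOTIF_bHLH	0	-
spB_TFs2_L1_01	MOTIF_bHLH	38	-
spB_TF_L2_01	MOTIF_bHLH	352	-
spB_TF_L2_02	MOTIF_bHLH	115	+
spB_TF_L2_03	MOTIF_bHLH	253	-
spB_TFs2_L2_01	MOTIF_bHLH	134	+
spB_TF_L3_01	MOTIF_NAC	15	-
spB_TF_L3_02	MOTIF_MYB_related	99	-
spB_TF_L3_03	MOTIF_C2H2	209	+
spB_TFs2_L3_01	MOTIF_C2H2	16	-
spB_TF_L4_01	MOTIF_MYB	456	+
spB_TF_L4_02	MOTIF_bHLH	409	+
spB_TF_L4_03	MOTIF_GRAS	196	-
spB_TFs2_L4_01	MOTIF_bHLH	138	-
spB_E01_caro	MOTIF_NAC	489	+
spB_E01_caro	MOTIF_GRAS	426	-
spB_E02_caro	MOTIF_GRAS	211	-
spB_E02_caro	MOTIF_B3	140	+
spB_E03_caro	MOTIF_NAC	46	+
spB_E04_chlo	MOTIF_GRAS	191	+
spB_E05_chlo	MOTIF_NAC	385	-
spB_E06_anth	MOTIF_GRAS	440	-
spB_E07_anth	MOTIF_NAC	227	+
spB_E08_flav	MOTIF_GRAS	143	-
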