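gene	motif	start	strand
spA_TF_L1_02	MOTIF_bHLH	443	+
spA_TF_L1_03	MOTIF_bHLH	320	-
spA_TFs1_L1_01	MOTIF_bHLH	345	-
spA_TF_L2_01	MOTIF_bHLH	75	-
spA_TF_L2_02	MOTIF_bHLH	294	-
spA_TF_L2_03	MOTIF_bHLH	74	-
spA_TFs1_L2_01	MOTIF_bHLH	445	-
spA_TF_L3_01	MOTIF_NAC	84	-
spA_TF_L3_02	MOTIF_MYB_related	363	+
spA_TF_L3_03	MOTIF_C2H2	434	+
spA_TFs1_L3_01	MOTIF_C2H2	378	+
spA_TF_L4_01	MOTIF_MYB	379	+
spA_TF_L4_02	MOTIF_bHLH	99	-
spA_TF_L4_03	MOTIF_GRAS	166	+
spA_TFs1_L4_01	MOTIF_bHLH	202	+
spA_E01_caro	MOTIF_NAC	415	+
spA_E01_caro	MOTIF_GRAS	30	+
spA_E02_caro	MOTIF_GRAS	193	+
spA_E02_caro	MOTIF_B3	288	+
spA_E03_caro	MOTIF_NAC	228	-
spA_E04_chlo	MOTIF_GRAS	389	-
spA_E05_chlo	MOTIF_NAC	316	-
spA_E06_anth	MOTIF_GRAS	477	+
spA_E07_anth	MOTIF_NAC	346	-
spA_E08_flav	MOTIF_GRAS	469	-
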