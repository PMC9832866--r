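gene_id	is_tf	tf_family	pathway	length
spA_TF_L1_01	TRUE	bHLH	none	2949
spA_TF_L1_02	TRUE	WRKY	none	1135
spA_TF_L1_03	TRUE	ERF	none	858
spA_TFs1_L1_01	TRUE	B3	none	1632
spA_TF_L2_01	TRUE	MYB_related	none	1755
spA_TF_L2_02	TRUE	C2H2	none	2020
spA_TF_L2_03	TRUE	NAC	none	771
spA_TFs1_L2_01	TRUE	WD40	none	2215
spA_TF_L3_01	TRUE	GRAS	none	2950
spA_TF_L3_02	TRUE	MYB	none	1508
spA_TF_L3_03	TRUE	bHLH	none	658
spA_TFs1_L3_01	TRUE	WRKY	none	906
spA_TF_L4_01	TRUE	ERF	none	2589
spA_TF_L4_02	TRUE	B3	none	1556
spA_TF_L4_03	TRUE	MYB_related	none	1897
spA_TFs1_L4_01	TRUE	C2H2	none	622
spA_E01_caro	FALSE		carotenoid	1471
spA_E02_caro	FALSE		carotenoid	2084
spA_E03_caro	FALSE		carotenoid	574
spA_E04_chlo	FALSE		chlorophyll	2419
spA_E05_chlo	FALSE		chlorophyll	2435
spA_E06_anth	FALSE		anthocyanin	2083
spA_E07_anth	FALSE		anthocyanin	2303
spA_E08_flav	FALSE		flavonol	2774
spA_BG001	FALSE		none	1393
spA_BG002	FALSE		none	2016
spA_BG003	FALSE		none	1725
spA_BG004	FALSE		none	1012
spA_BG005	FALSE		none	2208
spA_BG006	FALSE		none	2127
spA_BG007	FALSE		none	1732
spA_BG008	FALSE		none	1561
spA_BG009	FALSE		none	1902
spA_BG010	FALSE		none	2314
spA_BG011	FALSE		none	1273
spA_BG012	FALSE		none	2249
spA_BULK01	FALSE		none	2379
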