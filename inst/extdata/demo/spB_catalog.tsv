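gene_id	is_tf	tf_family	pathway	length
spB_TF_L1_01	TRUE	bHLH	none	2163
spB_TF_L1_02	TRUE	WRKY	none	926
spB_TF_L1_03	TRUE	ERF	none	725
spB_TFs2_L1_01	TRUE	B3	none	1064
spB_TF_L2_01	TRUE	MYB_related	none	626
spB_TF_L2_02	TRUE	C2H2	none	1672
spB_TF_L2_03	TRUE	NAC	none	641
spB_TFs2_L2_01	TRUE	WD40	none	1869
spB_TF_L3_01	TRUE	GRAS	none	1584
spB_TF_L3_02	TRUE	MYB	none	1982
spB_TF_L3_03	TRUE	bHLH	none	1956
spB_TFs2_L3_01	TRUE	WRKY	none	1812
spB_TF_L4_01	TRUE	ERF	none	2367
spB_TF_L4_02	TRUE	B3	none	1294
spB_TF_L4_03	TRUE	MYB_related	none	1890
spB_TFs2_L4_01	TRUE	C2H2	none	1567
spB_E01_caro	FALSE		carotenoid	1567
spB_E02_caro	FALSE		carotenoid	1198
spB_E03_caro	FALSE		carotenoid	927
spB_E04_chlo	FALSE		chlorophyll	2772
spB_E05_chlo	FALSE		chlorophyll	2940
spB_E06_anth	FALSE		anthocyanin	2129
spB_E07_anth	FALSE		anthocyanin	2739
spB_E08_flav	FALSE		flavonol	2377
spB_BG001	FALSE		none	1991
spB_BG002	FALSE		none	2690
spB_BG003	FALSE		none	2657
spB_BG004	FALSE		none	1005
spB_BG005	FALSE		none	2251
spB_BG006	FALSE		none	2061
spB_BG007	FALSE		none	1010
spB_BG008	FALSE		none	1932
spB_BG009	FALSE		none	565
spB_BG010	FALSE		none	1395
spB_BG011	FALSE		none	553
spB_BG012	FALSE		none	2475
spB_BULK01	FALSE		none	1573
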