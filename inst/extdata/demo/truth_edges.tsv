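regulator	target	species	scope	type
spA_TF_L1_01	spA_TF_L1_02	1	both	tf
spB_TF_L1_01	spB_TF_L1_02	2	both	tf
spA_TF_L1_01	spA_TF_L1_03	1	both	tf
spB_TF_L1_01	spB_TF_L1_03	2	both	tf
spA_TF_L1_01	spA_TFs1_L1_01	1	species1	tf
spB_TF_L1_01	spB_TFs2_L1_01	2	species2	tf
spA_TF_L1_01	spA_TF_L2_01	1	both	tf
spB_TF_L1_01	spB_TF_L2_01	2	both	tf
spA_TF_L1_01	spA_TF_L2_02	1	both	tf
spB_TF_L1_01	spB_TF_L2_02	2	both	tf
spA_TF_L1_01	spA_TF_L2_03	1	both	tf
spB_TF_L1_01	spB_TF_L2_03	2	both	tf
spA_TF_L1_01	spA_TFs1_L2_01	1	species1	tf
spB_TF_L1_01	spB_TFs2_L2_01	2	species2	tf
spA_TF_L2_03	spA_TF_L3_01	1	both	tf
spB_TF_L2_03	spB_TF_L3_01	2	both	tf
spA_TF_L2_01	spA_TF_L3_02	1	both	tf
spB_TF_L2_01	spB_TF_L3_02	2	both	tf
spA_TF_L2_02	spA_TF_L3_03	1	both	tf
spB_TF_L2_02	spB_TF_L3_03	2	both	tf
spA_TF_L2_02	spA_TFs1_L3_01	1	species1	tf
spB_TF_L2_02	spB_TFs2_L3_01	2	species2	tf
spA_TF_L3_02	spA_TF_L4_01	1	both	tf
spB_TF_L3_02	spB_TF_L4_01	2	both	tf
spA_TF_L3_03	spA_TF_L4_02	1	both	tf
spB_TF_L3_03	spB_TF_L4_02	2	both	tf
spA_TF_L3_01	spA_TF_L4_03	1	both	tf
spB_TF_L3_01	spB_TF_L4_03	2	both	tf
spA_TF_L3_03	spA_TFs1_L4_01	1	species1	tf
spB_TF_L3_03	spB_TFs2_L4_01	2	species2	tf
spA_TF_L2_03	spA_E01_caro	1	both	enzyme
spA_TF_L3_01	spA_E01_caro	1	both	enzyme
spB_TF_L2_03	spB_E01_caro	2	both	enzyme
spB_TF_L3_01	spB_E01_caro	2	both	enzyme
spA_TF_L3_01	spA_E02_caro	1	both	enzyme
spA_TF_L4_02	spA_E02_caro	1	both	enzyme
spB_TF_L3_01	spB_E02_caro	2	both	enzyme
spB_TF_L4_02	spB_E02_caro	2	both	enzyme
spA_TF_L2_03	spA_E03_caro	1	species1	enzyme
spB_TF_L2_03	spB_E03_caro	2	species2	enzyme
spA_TF_L3_01	spA_E04_chlo	1	both	enzyme
spB_TF_L3_01	spB_E04_chlo	2	both	enzyme
spA_TF_L2_03	spA_E05_chlo	1	both	enzyme
spB_TF_L2_03	spB_E05_chlo	2	both	enzyme
spA_TF_L3_01	spA_E06_anth	1	both	enzyme
spB_TF_L3_01	spB_E06_anth	2	both	enzyme
spA_TF_L2_03	spA_E07_anth	1	both	enzyme
spB_TF_L2_03	spB_E07_anth	2	both	enzyme
spA_TF_L3_01	spA_E08_flav	1	both	enzyme
spB_TF_L3_01	spB_E08_flav	2	both	enzyme
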