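gene1	gene2
spA_TF_L1_01	spB_TF_L1_01
spA_TF_L1_02	spB_TF_L1_02
spA_TF_L1_03	spB_TF_L1_03
spA_TF_L2_01	spB_TF_L2_01
spA_TF_L2_02	spB_TF_L2_02
spA_TF_L2_03	spB_TF_L2_03
spA_TF_L3_01	spB_TF_L3_01
spA_TF_L3_02	spB_TF_L3_02
spA_TF_L3_03	spB_TF_L3_03
spA_TF_L4_01	spB_TF_L4_01
spA_TF_L4_02	spB_TF_L4_02
spA_TF_L4_03	spB_TF_L4_03
spA_E01_caro	spB_E01_caro
spA_E02_caro	spB_E02_caro
spA_E03_caro	spB_E03_caro
spA_E04_chlo	spB_E04_chlo
spA_E05_chlo	spB_E05_chlo
spA_E06_anth	spB_E06_anth
spA_E07_anth	spB_E07_anth
spA_E08_flav	spB_E08_flav
spA_BG002	spB_BG002
spA_BG003	spB_BG003
spA_BG004	spB_BG004
spA_BG005	spB_BG005
spA_BG006	spB_BG006
spA_BG007	spB_BG007
spA_BG008	spB_BG008
spA_BG009	spB_BG009
spA_BG010	spB_BG010
spA_BG011	spB_BG011
spA_BG012	spB_BG012
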