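species	gene	level
spA	spA_TF_L1_01	1
spA	spA_TF_L1_02	2
spA	spA_TF_L1_03	2
spA	spA_TFs1_L1_01	2
spA	spA_TF_L2_01	2
spA	spA_TF_L2_02	2
spA	spA_TF_L2_03	2
spA	spA_TFs1_L2_01	2
spA	spA_TF_L3_01	3
spA	spA_TF_L3_02	3
spA	spA_TF_L3_03	3
spA	spA_TFs1_L3_01	3
spA	spA_TF_L4_01	4
spA	spA_TF_L4_02	4
spA	spA_TF_L4_03	4
spA	spA_TFs1_L4_01	4
spB	spB_TF_L1_01	1
spB	spB_TF_L1_02	2
spB	spB_TF_L1_03	2
spB	spB_TFs2_L1_01	2
spB	spB_TF_L2_01	2
spB	spB_TF_L2_02	2
spB	spB_TF_L2_03	2
spB	spB_TFs2_L2_01	2
spB	spB_TF_L3_01	3
spB	spB_TF_L3_02	3
spB	spB_TF_L3_03	3
spB	spB_TFs2_L3_01	3
spB	spB_TF_L4_01	4
spB	spB_TF_L4_02	4
spB	spB_TF_L4_03	4
spB	spB_TFs2_L4_01	4
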