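##gff-version 3
##source-version rtracklayer 1.62.0
##date 2026-09-28
spA_TF_L1_01_ctg	rtracklayer	gene	501	800	.	+	.	ID=spA_TF_L1_01
spA_TF_L1_02_ctg	rtracklayer	gene	1	300	.	-	.	ID=spA_TF_L1_02
spA_TF_L1_03_ctg	rtracklayer	gene	501	800	.	+	.	ID=spA_TF_L1_03
spA_TFs1_L1_01_ctg	rtracklayer	gene	1	300	.	-	.	ID=spA_TFs1_L1_01
spA_TF_L2_01_ctg	rtracklayer	gene	501	800	.	+	.	ID=spA_TF_L2_01
spA_TF_L2_02_ctg	rtracklayer	gene	1	300	.	-	.	ID=spA_TF_L2_02
spA_TF_L2_03_ctg	rtracklayer	gene	501	800	.	+	.	ID=spA_TF_L2_03
spA_TFs1_L2_01_ctg	rtracklayer	gene	1	300	.	-	.	ID=spA_TFs1_L2_01
spA_TF_L3_01_ctg	rtracklayer	gene	501	800	.	+	.	ID=spA_TF_L3_01
spA_TF_L3_02_ctg	rtracklayer	gene	1	300	.	-	.	ID=spA_TF_L3_02
spA_TF_L3_03_ctg	rtracklayer	gene	501	800	.	+	.	ID=spA_TF_L3_03
spA_TFs1_L3_01_ctg	rtracklayer	gene	1	300	.	-	.	ID=spA_TFs1_L3_01
spA_TF_L4_01_ctg	rtracklayer	gene	501	800	.	+	.	ID=spA_TF_L4_01
spA_TF_L4_02_ctg	rtracklayer	gene	1	300	.	-	.	ID=spA_TF_L4_02
spA_TF_L4_03_ctg	rtracklayer	gene	501	800	.	+	.	ID=spA_TF_L4_03
spA_TFs1_L4_01_ctg	rtracklayer	gene	1	300	.	-	.	ID=spA_TFs1_L4_01
spA_E01_caro_ctg	rtracklayer	gene	501	800	.	+	.	ID=spA_E01_caro
spA_E02_caro_ctg	rtracklayer	gene	1	300	.	-	.	ID=spA_E02_caro
spA_E03_caro_ctg	rtracklayer	gene	501	800	.	+	.	ID=spA_E03_caro
spA_E04_chlo_ctg	rtracklayer	gene	1	300	.	-	.	ID=spA_E04_chlo
spA_E05_chlo_ctg	rtracklayer	gene	501	800	.	+	.	ID=spA_E05_chlo
spA_E06_anth_ctg	rtracklayer	gene	1	300	.	-	.	ID=spA_E06_anth
spA_E07_anth_ctg	rtracklayer	gene	501	800	.	+	.	ID=spA_E07_anth
spA_E08_flav_ctg	rtracklayer	gene	1	300	.	-	.	ID=spA_E08_flav
spA_BG001_ctg	rtracklayer	gene	501	800	.	+	.	ID=spA_BG001
spA_BG002_ctg	rtracklayer	gene	1	300	.	-	.	ID=spA_BG002
spA_BG003_ctg	rtracklayer	gene	501	800	.	+	.	ID=spA_BG003
spA_BG004_ctg	rtracklayer	gene	1	300	.	-	.	ID=spA_BG004
spA_BG005_ctg	rtracklayer	gene	501	800	.	+	.	ID=spA_BG005
spA_BG006_ctg	rtracklayer	gene	1	300	.	-	.	ID=spA_BG006
spA_BG007_ctg	rtracklayer	gene	501	800	.	+	.	ID=spA_BG007
spA_BG008_ctg	rtracklayer	gene	1	300	.	-	.	ID=spA_BG008
spA_BG009_ctg	rtracklayer	gene	501	800	.	+	.	ID=spA_BG009
spA_BG010_ctg	rtracklayer	gene	1	300	.	-	.	ID=spA_BG010
spA_BG011_ctg	rtracklayer	gene	501	800	.	+	.	ID=spA_BG011
spA_BG012_ctg	rtracklayer	gene	1	300	.	-	.	ID=spA_BG012
spA_BULK01_ctg	rtracklayer	gene	501	800	.	+	.	ID=spA_BULK01
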