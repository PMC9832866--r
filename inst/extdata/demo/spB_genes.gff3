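##gff-version 3
##source-version rtracklayer 1.62.0
##date 2026-09-28
spB_TF_L1_01_ctg	rtracklayer	gene	501	800	.	+	.	ID=spB_TF_L1_01
spB_TF_L1_02_ctg	rtracklayer	gene	1	300	.	-	.	ID=spB_TF_L1_02
spB_TF_L1_03_ctg	rtracklayer	gene	501	800	.	+	.	ID=spB_TF_L1_03
spB_TFs2_L1_01_ctg	rtracklayer	gene	1	300	.	-	.	ID=spB_TFs2_L1_01
spB_TF_L2_01_ctg	rtracklayer	gene	501	800	.	+	.	ID=spB_TF_L2_01
spB_TF_L2_02_ctg	rtracklayer	gene	1	300	.	-	.	ID=spB_TF_L2_02
spB_TF_L2_03_ctg	rtracklayer	gene	501	800	.	+	.	ID=spB_TF_L2_03
spB_TFs2_L2_01_ctg	rtracklayer	gene	1	300	.	-	.	ID=spB_TFs2_L2_01
spB_TF_L3_01_ctg	rtracklayer	gene	501	800	.	+	.	ID=spB_TF_L3_01
spB_TF_L3_02_ctg	rtracklayer	gene	1	300	.	-	.	ID=spB_TF_L3_02
spB_TF_L3_03_ctg	rtracklayer	gene	501	800	.	+	.	ID=spB_TF_L3_03
spB_TFs2_L3_01_ctg	rtracklayer	gene	1	300	.	-	.	ID=spB_TFs2_L3_01
spB_TF_L4_01_ctg	rtracklayer	gene	501	800	.	+	.	ID=spB_TF_L4_01
spB_TF_L4_02_ctg	rtracklayer	gene	1	300	.	-	.	ID=spB_TF_L4_02
spB_TF_L4_03_ctg	rtracklayer	gene	501	800	.	+	.	ID=spB_TF_L4_03
spB_TFs2_L4_01_ctg	rtracklayer	gene	1	300	.	-	.	ID=spB_TFs2_L4_01
spB_E01_caro_ctg	rtracklayer	gene	501	800	.	+	.	ID=spB_E01_caro
spB_E02_caro_ctg	rtracklayer	gene	1	300	.	-	.	ID=spB_E02_caro
spB_E03_caro_ctg	rtracklayer	gene	501	800	.	+	.	ID=spB_E03_caro
spB_E04_chlo_ctg	rtracklayer	gene	1	300	.	-	.	ID=spB_E04_chlo
spB_E05_chlo_ctg	rtracklayer	gene	501	800	.	+	.	ID=spB_E05_chlo
spB_E06_anth_ctg	rtracklayer	gene	1	300	.	-	.	ID=spB_E06_anth
spB_E07_anth_ctg	rtracklayer	gene	501	800	.	+	.	ID=spB_E07_anth
spB_E08_flav_ctg	rtracklayer	gene	1	300	.	-	.	ID=spB_E08_flav
spB_BG001_ctg	rtracklayer	gene	501	800	.	+	.	ID=spB_BG001
spB_BG002_ctg	rtracklayer	gene	1	300	.	-	.	ID=spB_BG002
spB_BG003_ctg	rtracklayer	gene	501	800	.	+	.	ID=spB_BG003
spB_BG004_ctg	rtracklayer	gene	1	300	.	-	.	ID=spB_BG004
spB_BG005_ctg	rtracklayer	gene	501	800	.	+	.	ID=spB_BG005
spB_BG006_ctg	rtracklayer	gene	1	300	.	-	.	ID=spB_BG006
spB_BG007_ctg	rtracklayer	gene	501	800	.	+	.	ID=spB_BG007
spB_BG008_ctg	rtracklayer	gene	1	300	.	-	.	ID=spB_BG008
spB_BG009_ctg	rtracklayer	gene	501	800	.	+	.	ID=spB_BG009
spB_BG010_ctg	rtracklayer	gene	1	300	.	-	.	ID=spB_BG010
spB_BG011_ctg	rtracklayer	gene	501	800	.	+	.	ID=spB_BG011
spB_BG012_ctg	rtracklayer	gene	1	300	.	-	.	ID=spB_BG012
spB_BULK01_ctg	rtracklayer	gene	501	800	.	+	.	ID=spB_BULK01
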