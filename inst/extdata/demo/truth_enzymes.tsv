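gene	species	pathway	level	is_hub	rewired
spA_E01_caro	1	carotenoid	2	TRUE	FALSE
spB_E01_caro	2	carotenoid	2	TRUE	FALSE
spA_E02_caro	1	carotenoid	3	TRUE	FALSE
spB_E02_caro	2	carotenoid	3	TRUE	FALSE
spA_E03_caro	1	carotenoid	2	FALSE	TRUE
spB_E03_caro	2	carotenoid	2	FALSE	TRUE
spA_E04_chlo	1	chlorophyll	3	FALSE	FALSE
spB_E04_chlo	2	chlorophyll	3	FALSE	FALSE
spA_E05_chlo	1	chlorophyll	2	FALSE	FALSE
spB_E05_chlo	2	chlorophyll	2	FALSE	FALSE
spA_E06_anth	1	anthocyanin	3	FALSE	FALSE
spB_E06_anth	2	anthocyanin	3	FALSE	FALSE
spA_E07_anth	1	anthocyanin	2	FALSE	FALSE
spB_E07_anth	2	anthocyanin	2	FALSE	FALSE
spA_E08_flav	1	flavonol	3	FALSE	FALSE
spB_E08_flav	2	flavonol	3	FALSE	FALSE
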