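gene_id	T1_R1	T1_R2	T1_R3	T1_R4	T1_R5	T2_R1	T2_R2	T2_R3	T2_R4	T2_R5	T3_R1	T3_R2	T3_R3	T3_R4	T3_R5	T4_R1	T4_R2	T4_R3	T4_R4	T4_R5	T5_R1	T5_R2	T5_R3	T5_R4	T5_R5
spA_TF_L1_01	8497	8890	9738	8056	7840	1994	2007	1577	1982	1327	905	516	973	951	793	192	321	215	245	233	153	283	291	294	165
spA_TF_L1_02	6027	3403	4205	5416	4553	1278	1001	543	1014	1269	444	252	454	395	451	212	155	106	246	187	173	128	142	184	155
spA_TF_L1_03	4454	2497	4104	2297	2559	451	403	465	863	620	301	218	139	218	107	91	88	64	48	83	34	46	74	86	80
spA_TFs1_L1_01	4787	3067	3851	3047	3819	1111	899	722	733	740	399	339	264	391	288	96	47	141	158	126	84	115	90	69	114
spA_TF_L2_01	3476	2308	1758	1677	1856	2105	986	2294	1355	1617	542	692	876	609	449	161	321	296	320	255	30	73	29	37	35
spA_TF_L2_02	2004	2037	1581	2805	1726	2310	1794	2170	1108	1972	750	1067	640	1111	655	309	283	486	432	239	67	77	62	48	56
spA_TF_L2_03	1211	2244	2047	1922	861	849	658	1216	1166	798	360	437	391	398	417	155	259	253	118	213	28	29	40	16	39
spA_TFs1_L2_01	3886	7849	6039	5974	5704	3910	7405	5193	4100	6445	2692	2608	2488	2217	1391	890	593	683	542	816	115	54	94	157	119
spA_TF_L3_01	737	346	571	447	573	1324	1331	1399	1741	1555	1185	1035	1402	1393	1432	616	493	529	623	519	63	28	57	36	48
spA_TF_L3_02	550	557	450	412	554	1529	1150	1076	1129	937	1203	800	1119	705	869	827	504	482	331	457	16	26	23	26	16
spA_TF_L3_03	187	321	188	237	259	541	779	484	615	476	412	692	558	475	645	441	216	239	219	264	13	19	14	16	17
spA_TFs1_L3_01	367	329	324	281	356	1155	1568	1003	783	814	965	890	1212	1095	991	310	472	444	302	478	22	11	27	11	26
spA_TF_L4_01	466	342	500	378	362	3317	5574	4238	3975	4104	5660	5842	9486	5175	6682	7076	2986	5991	5361	3864	186	145	168	155	116
spA_TF_L4_02	148	144	161	187	115	944	842	1044	801	519	1198	1022	922	1079	973	837	1031	664	522	1150	71	53	26	68	35
spA_TF_L4_03	112	335	265	262	288	1495	1938	1870	1337	1426	2720	2310	1975	2482	2980	1533	1572	2108	2094	1869	85	63	67	67	71
spA_TFs1_L4_01	41	60	77	74	67	553	391	235	344	402	742	462	568	662	826	514	581	329	402	321	29	16	23	26	19
spA_E01_caro	388	258	479	618	646	2844	1544	1638	1607	1735	147	372	277	272	225	215	251	310	274	329	19	12	23	11	17
spA_E02_caro	423	472	595	510	588	1880	1746	1708	1421	1598	6845	8110	6182	5041	6170	680	856	891	795	1075	71	65	72	45	65
spA_E03_caro	1258	1469	1303	816	771	1412	1296	1732	1479	1188	99	197	153	184	177	158	428	305	297	378	38	9	36	22	51
spA_E04_chlo	1849	1886	1750	2098	1442	1145	1578	1242	1053	857	5628	7466	9307	6687	6629	916	773	768	1091	1058	64	100	122	71	58
spA_E05_chlo	3895	6263	5445	4971	2916	4355	3653	3411	3588	2905	779	874	480	527	567	1685	1846	1621	1595	1432	123	133	173	107	115
spA_E06_anth	545	575	591	616	807	2212	1733	2680	1583	1847	3669	4983	6343	4913	3657	355	409	334	307	303	78	72	41	61	118
spA_E07_anth	1868	2421	2082	2346	1983	884	631	843	815	942	2374	1605	1574	2665	2215	254	150	178	152	120	94	49	81	67	78
spA_E08_flav	934	651	861	1133	1076	8180	4505	7089	7429	5805	6104	4109	4827	4257	3484	690	808	627	712	574	237	170	172	119	191
spA_BG001	204	311	377	309	297	429	269	428	462	269	377	453	268	270	216	256	333	327	348	318	359	352	398	373	352
spA_BG002	704	831	569	739	575	627	1135	674	545	538	593	401	661	747	621	632	746	748	610	962	929	588	538	801	601
spA_BG003	577	540	406	424	726	431	440	504	514	599	796	742	334	640	685	801	830	746	668	743	487	672	622	516	529
spA_BG004	305	330	508	398	382	449	507	356	484	467	374	370	298	510	365	436	301	426	419	397	607	402	595	469	385
spA_BG005	788	943	810	701	972	915	1230	840	946	1061	860	996	1023	900	740	1040	1222	634	832	987	591	692	842	512	1081
spA_BG006	748	820	1128	731	1494	809	719	657	1305	1018	1649	672	1038	890	848	829	1071	933	987	1021	909	1026	821	914	654
spA_BG007	657	1617	955	566	956	803	1032	765	511	709	665	752	981	1090	367	808	746	910	672	829	998	769	692	974	721
spA_BG008	1143	939	835	1051	459	591	764	578	1163	682	532	1028	680	887	818	725	709	637	524	1019	957	661	834	636	715
spA_BG009	913	867	513	763	995	639	760	1077	1001	557	987	835	694	924	756	677	811	702	748	983	1026	686	704	432	787
spA_BG010	347	515	327	347	261	468	365	345	399	316	359	229	259	622	254	334	476	365	255	421	247	319	302	243	268
spA_BG011	294	473	646	328	447	482	754	636	519	349	311	387	287	532	423	323	678	424	503	254	337	368	538	439	539
spA_BG012	589	622	763	645	644	641	510	392	362	587	689	779	485	933	647	619	476	1154	796	529	560	741	516	487	908
spA_BULK01	4070	2001	3055	1947	2891	9144	4824	8382	7044	7722	10598	16343	11323	12806	15520	72461	46078	28212	67059	58406	66831	64701	61305	76967	67895
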