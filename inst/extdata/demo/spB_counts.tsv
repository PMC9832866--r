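gene_id	T1_R1	T1_R2	T1_R3	T1_R4	T1_R5	T2_R1	T2_R2	T2_R3	T2_R4	T2_R5	T3_R1	T3_R2	T3_R3	T3_R4	T3_R5	T4_R1	T4_R2	T4_R3	T4_R4	T4_R5	T5_R1	T5_R2	T5_R3	T5_R4	T5_R5
spB_TF_L1_01	2382	2357	1672	3000	3144	830	397	620	636	464	159	208	222	256	144	49	89	82	97	99	69	69	56	99	69
spB_TF_L1_02	6708	4200	4719	4541	4975	959	961	1219	995	739	271	356	449	439	406	137	149	227	127	118	156	103	138	95	133
spB_TF_L1_03	2021	1423	1380	1843	1858	449	379	520	271	371	175	130	155	138	107	72	86	67	117	42	55	69	86	59	36
spB_TFs2_L1_01	3303	4458	5817	6040	4399	565	1247	1284	908	890	212	318	334	313	276	80	182	207	120	146	116	107	96	78	96
spB_TF_L2_01	1146	726	1207	1399	757	865	538	585	786	676	323	405	325	474	359	153	101	116	112	104	11	38	28	20	18
spB_TF_L2_02	2118	1952	1890	2192	2259	1000	1320	1840	1967	1897	942	905	665	730	978	437	346	360	347	156	63	55	68	65	36
spB_TF_L2_03	1033	637	984	1132	438	787	940	587	563	666	313	279	355	193	400	115	137	163	119	74	15	18	9	14	8
spB_TFs2_L2_01	4149	2646	3733	2742	3344	2489	2233	2656	2851	2451	1357	1241	1523	1150	1132	414	426	532	580	404	48	66	60	75	86
spB_TF_L3_01	725	527	568	441	563	1976	1480	1396	1837	1836	1586	1101	886	1138	1441	702	402	480	437	570	19	29	17	25	33
spB_TF_L3_02	540	692	757	674	912	2802	2296	1721	1698	1437	1158	1465	1343	1325	1509	440	668	702	492	1019	33	39	54	58	27
spB_TF_L3_03	588	1240	1036	596	948	2689	2492	4177	2486	3903	1311	1631	1998	2568	1979	794	809	912	666	912	30	28	50	27	47
spB_TFs2_L3_01	478	366	302	372	353	879	1282	1214	1256	897	941	1178	1126	820	796	309	324	231	422	281	21	24	18	12	15
spB_TF_L4_01	274	342	302	225	320	1078	2126	1594	2377	1595	2158	2370	3110	2617	2447	2400	2639	2399	1873	2838	49	111	99	111	75
spB_TF_L4_02	113	78	132	97	66	1552	777	1339	914	1158	1092	2048	1610	1144	1513	963	1318	1108	812	1089	44	36	35	50	23
spB_TF_L4_03	313	485	356	407	344	3049	3082	3459	3311	2726	4118	4058	5810	5419	5850	5280	3764	3903	4326	3291	127	176	147	162	85
spB_TFs2_L4_01	291	210	248	373	197	2341	2186	3073	2593	2718	3144	3661	1969	3458	4303	2227	2497	2824	2757	2448	81	53	132	99	57
spB_E01_caro	705	1101	1484	1519	830	3715	3565	3450	2939	2893	512	497	293	319	506	513	773	525	505	432	49	39	42	45	32
spB_E02_caro	306	282	205	374	271	500	592	462	813	696	2528	3396	3062	3568	3321	576	641	680	696	654	20	59	14	35	40
spB_E03_caro	1492	2303	1909	2785	1605	376	463	426	316	241	297	465	312	388	330	419	401	464	363	533	44	40	19	24	29
spB_E04_chlo	2026	1528	1833	2027	1330	1359	1458	1104	983	1052	2388	2534	1817	2585	2301	2339	1611	2747	2497	2409	39	45	57	48	64
spB_E05_chlo	2391	5837	3509	4497	6338	2810	2761	2322	1689	1870	5027	4697	4332	4351	6182	315	502	341	328	436	191	113	106	105	191
spB_E06_anth	763	737	524	901	789	1301	1213	1188	1701	1430	3169	2769	4104	3304	3914	455	299	248	330	341	62	81	80	56	78
spB_E07_anth	4687	5789	4308	4866	4150	3472	2888	4469	3477	6392	600	578	644	885	679	1787	2083	1924	2040	2562	155	109	149	124	139
spB_E08_flav	1140	1088	1133	948	1311	1195	1208	1286	1418	990	1057	908	984	958	1024	1382	2283	1696	2326	1958	35	59	28	43	52
spB_BG001	547	487	800	579	468	503	724	514	380	524	413	440	660	484	688	499	507	502	477	573	445	415	654	452	605
spB_BG002	1580	1535	1463	1598	1452	1176	1239	1623	1515	1508	1283	1447	1289	1625	1590	2005	1271	1538	2061	1072	1428	1250	1334	1120	1682
spB_BG003	751	641	465	1251	988	687	789	862	727	1050	728	803	1003	791	859	702	718	849	768	676	508	696	644	856	852
spB_BG004	225	198	193	203	192	176	238	283	162	246	243	132	190	148	121	293	306	193	261	269	181	213	152	154	192
spB_BG005	999	752	1175	1466	935	1182	1384	1356	1115	675	966	1169	995	1036	1135	834	1061	1187	768	762	992	1481	981	1347	976
spB_BG006	688	465	380	411	396	649	500	270	453	397	458	606	451	487	453	335	515	356	614	431	501	607	539	576	478
spB_BG007	249	221	244	241	179	264	272	302	378	291	234	278	280	337	284	434	145	446	361	252	366	244	240	174	302
spB_BG008	968	627	1228	949	851	899	562	706	746	854	837	612	807	863	687	856	945	1009	1423	846	1018	894	655	742	633
spB_BG009	183	127	102	144	157	133	153	188	126	150	121	139	106	88	96	168	140	139	145	152	145	130	138	172	232
spB_BG010	423	246	426	268	501	453	377	429	366	239	523	401	663	392	510	370	369	276	262	282	322	346	313	390	272
spB_BG011	192	188	229	163	129	165	135	140	176	177	167	157	213	92	206	125	180	153	136	346	168	237	247	189	190
spB_BG012	811	435	1069	1081	819	923	970	921	744	1005	1290	737	1006	1038	664	801	833	914	663	761	628	1104	894	708	854
spB_BULK01	2276	1625	2918	2749	2667	16112	13212	11345	14861	9820	17508	15457	11815	15913	8776	31576	39103	27707	20701	22412	49759	32983	46005	41625	48621
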