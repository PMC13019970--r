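#FeatureID	home_1.entrance_IBZ.wm02	home_1.entrance_IBZ.wp00	home_1.entrance_IBZ.wp02	home_1.entrance_IBZ.wp04	home_1.entrance_IBZ.wp06	home_1.entrance_ABZ.wm02	home_1.entrance_ABZ.wp00	home_1.entrance_ABZ.wp02	home_1.entrance_ABZ.wp04	home_1.entrance_ABZ.wp06	home_1.LR_IBZ.wm02	home_1.LR_IBZ.wp00	home_1.LR_IBZ.wp02	home_1.LR_IBZ.wp04	home_1.LR_IBZ.wp06	home_1.LR_ABZ.wm02	home_1.LR_ABZ.wp00	home_1.LR_ABZ.wp02	home_1.LR_ABZ.wp04	home_1.LR_ABZ.wp06	control_1.entrance_IBZ.wm02	control_1.entrance_IBZ.wp00	control_1.entrance_IBZ.wp02	control_1.entrance_IBZ.wp04	control_1.entrance_IBZ.wp06	control_1.entrance_ABZ.wm02	control_1.entrance_ABZ.wp00	control_1.entrance_ABZ.wp02	control_1.entrance_ABZ.wp04	control_1.entrance_ABZ.wp06	control_1.LR_IBZ.wm02	control_1.LR_IBZ.wp00	control_1.LR_IBZ.wp02	control_1.LR_IBZ.wp04	control_1.LR_IBZ.wp06	control_1.LR_ABZ.wm02	control_1.LR_ABZ.wp00	control_1.LR_ABZ.wp02	control_1.LR_ABZ.wp04	control_1.LR_ABZ.wp06	home_1.soil.wp00.r1	home_1.soil.wp00.r2	home_1.soil.wp04.r1	home_1.soil.wp04.r2	blank.01	blank.02	blank.03
Soilgenus001	0	0	17	6	59	0	0	28	15	4	0	0	12	1	20	0	0	33	3	5	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	261	318	272	205	0	0	0
Soilgenus002	0	0	1	0	1	0	0	2	2	0	0	0	0	0	0	0	0	0	0	4	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	18	15	15	8	0	0	0
Soilgenus003	0	0	12	2	28	0	0	21	1	14	0	0	2	4	4	0	0	10	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	135	123	104	114	0	0	0
Soilgenus004	0	0	41	49	195	0	0	45	61	67	0	0	31	33	65	0	0	21	10	39	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	863	761	764	746	0	0	0
Soilgenus005	0	0	17	1	2	0	0	9	14	1	0	0	0	0	1	0	0	1	1	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	95	34	38	34	0	0	0
Soilgenus006	0	0	73	31	155	0	0	56	45	52	0	0	21	20	28	0	0	26	34	18	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	932	692	704	670	0	0	0
Soilgenus007	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	2	8	4	22	0	0	0
Soilgenus008	0	0	16	0	9	0	0	1	1	0	0	0	1	1	0	0	0	2	0	11	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	47	70	89	32	0	0	0
Soilgenus009	0	0	0	0	0	0	0	0	0	0	0	0	1	4	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	16	0	0	0	0	0
Soilgenus010	0	0	3	0	5	0	0	7	0	1	0	0	0	1	1	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	26	16	66	44	0	0	0
Soilgenus011	0	0	12	14	39	0	0	31	13	34	0	0	1	14	13	0	0	28	28	6	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	278	237	278	203	0	0	0
Soilgenus012	319	205	162	162	235	184	356	206	209	131	240	225	163	236	151	215	193	163	184	180	178	169	176	171	211	172	253	170	205	133	159	108	230	157	131	144	135	119	188	95	163	148	136	108	0	0	0
Staphylococcus	373	274	235	334	523	243	483	288	386	158	383	329	253	362	411	323	237	255	319	428	335	268	347	268	381	212	457	286	329	291	367	207	298	321	258	213	309	279	304	142	0	0	0	0	0	0	0
Streptococcus	232	202	120	185	262	191	178	124	193	88	165	247	229	225	184	146	69	160	138	254	150	154	133	135	206	186	261	195	160	209	204	115	199	181	111	183	100	187	154	82	0	0	0	0	0	0	0
Cutibacterium	312	305	214	268	349	282	467	248	319	269	397	422	228	344	317	244	167	330	293	309	349	237	260	310	336	188	304	271	303	320	304	199	327	218	223	174	202	301	343	138	0	0	0	0	0	0	0
Corynebacterium	73	54	44	46	62	88	87	60	72	31	112	64	52	85	88	82	45	92	66	98	20	42	80	40	81	28	94	66	26	58	67	48	46	179	75	83	53	52	53	17	0	0	0	0	0	0	0
Escherichia	65	9	9	22	30	9	35	14	16	6	23	17	3	34	23	17	9	5	21	26	20	14	11	16	13	13	22	15	18	11	8	19	8	4	3	6	1	29	6	7	0	0	0	0	0	0	0
Humangenus001	330	276	235	293	290	243	328	197	416	200	261	293	275	367	387	270	204	342	264	282	307	283	235	250	292	235	289	264	225	264	246	188	296	266	194	253	243	333	307	116	0	0	0	0	0	0	0
Humangenus002	80	73	37	41	78	64	103	56	113	42	80	166	72	66	107	78	75	66	81	55	120	74	67	62	65	74	81	68	61	45	94	67	81	56	69	44	54	65	102	24	0	0	0	0	0	0	0
Humangenus003	95	62	89	117	72	33	126	32	64	34	50	85	54	71	49	88	41	41	106	110	58	44	92	72	76	30	115	35	100	49	60	57	58	31	47	38	34	64	79	30	0	0	0	0	0	0	0
Outdoorgenus001	295	211	144	196	316	264	348	189	386	128	307	248	180	232	287	192	126	257	254	341	205	230	206	201	254	169	291	185	200	160	218	152	271	142	133	193	155	157	274	86	0	0	0	0	0	0	0
Outdoorgenus002	43	58	41	30	78	49	50	38	66	38	20	68	29	101	115	51	34	48	53	32	142	39	55	107	109	25	60	34	38	42	50	44	76	49	85	57	71	62	52	38	0	0	0	0	0	0	0
Outdoorgenus003	4	0	0	0	1	1	2	0	0	6	1	0	0	4	0	0	1	0	0	0	1	0	0	0	2	0	0	0	0	1	0	0	0	1	4	3	1	0	0	0	0	0	0	0	0	0	0
Outdoorgenus004	149	145	125	126	161	110	234	110	177	92	185	141	115	172	181	165	74	116	128	165	143	174	112	122	179	134	168	130	158	174	148	97	176	99	118	128	66	143	123	85	0	0	0	0	0	0	0
Outdoorgenus005	0	1	1	20	12	2	0	2	31	3	1	4	0	2	6	5	0	3	0	4	2	2	8	7	0	0	1	2	1	7	1	3	0	3	4	3	3	7	0	0	0	0	0	0	0	0	0
Outdoorgenus006	21	37	25	25	66	16	24	39	53	19	25	42	26	73	91	29	6	24	55	53	25	27	45	42	46	8	39	28	50	35	51	22	39	35	52	9	16	32	44	47	0	0	0	0	0	0	0
Outdoorgenus007	23	16	25	26	56	15	61	36	18	8	30	11	8	32	33	26	37	45	59	68	10	20	29	29	60	53	27	18	22	19	31	25	33	27	2	58	33	32	41	16	0	0	0	0	0	0	0
Outdoorgenus008	61	23	27	42	32	40	95	29	103	28	26	42	22	115	36	24	27	27	56	54	48	14	23	42	36	30	41	20	41	36	35	37	33	34	50	27	37	22	54	45	0	0	0	0	0	0	0
Outdoorgenus009	43	24	34	36	40	32	67	39	36	57	28	43	11	48	18	30	45	8	27	22	33	35	52	16	22	32	50	30	41	52	27	29	41	34	21	60	9	36	60	28	0	0	0	0	0	0	0
Homegenus001	44	0	0	8	5	4	23	19	10	0	2	3	3	2	0	7	3	11	0	1	0	0	0	0	1	0	0	0	1	0	6	0	0	2	3	0	2	3	0	0	0	0	0	0	0	0	0
Homegenus002	78	51	47	68	75	91	70	36	45	41	64	53	58	70	22	47	39	39	79	45	76	103	56	71	87	96	55	102	49	114	97	80	59	65	80	75	38	99	77	52	0	0	0	0	0	0	0
Homegenus003	5	2	0	5	8	31	9	0	5	1	8	32	5	0	5	13	2	13	8	13	0	1	4	0	0	0	2	3	0	1	3	0	5	0	7	1	0	7	15	1	0	0	0	0	0	0	0
Homegenus004	98	135	87	83	95	52	97	54	125	38	85	83	64	178	70	88	45	102	103	94	81	59	41	61	114	54	104	86	63	52	72	52	68	93	38	85	52	49	79	41	0	0	0	0	0	0	0
Homegenus005	155	97	90	107	196	134	171	85	185	125	160	222	87	146	164	118	81	166	197	164	137	82	90	116	133	127	210	102	176	89	158	92	106	70	107	77	58	133	127	59	0	0	0	0	0	0	0
Homegenus006	110	70	34	68	114	89	91	62	144	35	69	110	99	104	82	97	41	110	60	85	86	85	93	47	139	68	63	65	81	90	121	47	46	58	70	57	50	80	58	48	0	0	0	0	0	0	0
Homegenus007	133	110	100	92	154	165	123	94	139	81	140	154	40	139	167	98	54	85	75	153	96	100	74	99	119	76	109	141	49	83	76	124	121	101	112	62	91	138	131	41	0	0	0	0	0	0	0
Homegenus008	19	47	12	22	41	18	19	45	34	18	26	24	22	28	67	36	25	19	10	13	63	61	31	22	46	49	70	51	41	52	19	41	85	45	36	52	39	54	73	18	0	0	0	0	0	0	0
Contamgenus001	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	787	778	716
Contamgenus002	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	105	88	108
Contamgenus003	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	174	196	217
Contamgenus004	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	434	438	459
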