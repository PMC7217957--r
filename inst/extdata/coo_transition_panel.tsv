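protein	modified_sequence	rt_min	precursor_charge	precursor_mz_library	fragment_series	fragment_index	fragment_charge	fragment_mz_library
IGHM	QIQVSWLR	80	2	515.2957	y	6	1	788.4413
IGHM	QIQVSWLR	80	2	515.2957	y	4	1	561.3143
IGHM	QIQVSWLR	80	2	515.2957	y	5	1	660.3828
IGHM	[PGQ]-QIQVSWLR	114	2	506.7823	y	4	1	561.3143
IGHM	[PGQ]-QIQVSWLR	114	2	506.7823	y	5	1	660.3828
IGHM	[PGQ]-QIQVSWLR	114	2	506.7823	y	6	1	788.4413
POSTN	AAAITSDILEALGR	116	2	700.8908	y	10	1	1074.579
POSTN	AAAITSDILEALGR	116	2	700.8908	y	9	1	973.5313
POSTN	AAAITSDILEALGR	116	2	700.8908	y	8	1	886.4993
PTN1	MGLIQTADQLR	82	2	623.3347	y	7	1	831.4319
PTN1	MGLIQTADQLR	82	2	623.3347	y	6	1	703.3734
PTN1	MGLIQTADQLR	82	2	623.3347	y	8	1	944.516
PTN1	FSYLAVIEGAK	100	2	599.3293	y	7	1	687.4036
PTN1	FSYLAVIEGAK	100	2	599.3293	y	8	1	800.4876
PTN1	FSYLAVIEGAK	100	2	599.3293	y	9	1	963.551
CD44	YGFIEGHVVIPR	82	3	462.9225	y	8	1	906.5156
CD44	YGFIEGHVVIPR	82	3	462.9225	y	5	1	583.3926
CD44	YGFIEGHVVIPR	82	3	462.9225	y	4	1	484.3242
CD44	ALSIGFETC[PPa]R	79	2	584.2950	y	6	1	783.3454
CD44	ALSIGFETC[PPa]R	79	2	584.2950	y	8	1	983.4615
CD44	ALSIGFETC[PPa]R	79	2	584.2950	y	5	1	726.3239
CD44	ESSETPDQFMTADETR	71	2	922.3862	y	11	1	1310.5681
CD44	ESSETPDQFMTADETR	71	2	922.3862	y	8	1	970.4299
CD44	ESSETPDQFMTADETR	71	2	922.3862	y	12	1	1411.6158
HG2A	DLISNNEQLPMLGR	103	2	800.4116	y	11	1	1258.6208
HG2A	DLISNNEQLPMLGR	103	2	800.4116	y	7	1	814.4604
HG2A	DLISNNEQLPMLGR	103	2	800.4116	y	10	1	1171.5889
HG2A	LTVTSQNLQLENLR	87	2	814.9520	y	11	1	1315.6964
HG2A	LTVTSQNLQLENLR	87	2	814.9520	y	10	1	1214.6488
HG2A	LTVTSQNLQLENLR	87	2	814.9520	y	8	1	999.5582
LUM	FNALQYLR	90	2	512.7823	y	6	1	763.4461
LUM	FNALQYLR	90	2	512.7823	y	4	1	579.325
LUM	FNALQYLR	90	2	512.7823	y	5	1	692.409
LUM	LPSGLPVSLLTLYLDNNK	142	3	653.0383	y	6	1	766.373
LUM	LPSGLPVSLLTLYLDNNK	142	3	653.0383	b	9	1	864.5189
LUM	LPSGLPVSLLTLYLDNNK	142	3	653.0383	y	8	1	980.5048
RPS15	GVDLDQLLDMSYEQLMQLYSAR	171	3	863.4172	y	8	1	981.5186
RPS15	GVDLDQLLDMSYEQLMQLYSAR	171	3	863.4172	y	9	1	1109.5771
RPS15	GVDLDQLLDMSYEQLMQLYSAR	171	3	863.4172	y	10	1	1238.6198
RPS15	GVDLDQLLDM[Oxi]SYEQLMQLYSAR	166	3	868.7488	y	8	1	981.5186
RPS15	GVDLDQLLDM[Oxi]SYEQLMQLYSAR	166	3	868.7488	y	9	1	1109.5771
RPS15	GVDLDQLLDM[Oxi]SYEQLMQLYSAR	166	3	868.7488	y	10	1	1238.6198
RPS15	DMIILPEMVGSMVGVYN[Dea]GK	142	3	685.3384	y	10	1	1012.4768
RPS15	DMIILPEMVGSMVGVYN[Dea]GK	142	3	685.3384	b	14	2	737.3611
RPS15	DMIILPEMVGSMVGVYN[Dea]GK	142	3	685.3384	y	14	2	734.8442
TOM22	LQMEQQQQLQQR	50	2	779.3937	y	10	1	1316.6376
TOM22	LQMEQQQQLQQR	50	2	779.3937	y	8	1	1056.5544
TOM22	LQMEQQQQLQQR	50	2	779.3937	y	9	1	1185.597
TOM22	LWGLTEMFPER	115	2	689.8448	y	9	1	1079.519
TOM22	LWGLTEMFPER	115	2	689.8448	y	7	1	909.4135
TOM22	LWGLTEMFPER	115	2	689.8448	y	6	1	808.3658
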