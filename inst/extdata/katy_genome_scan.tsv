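# Genome-wide SSR distortion scan of 'Katy' selfing populations (K x K 05/06)
# position_mb: peach genome scaffold position; position_cm: apricot map position
lg	locus	position_mb	position_cm	seg_type	A	H	B
1	Gol051	4.69	0.0	<abxab>	12	22	12
1	EPPCU0027	9.51	30.7	<abxab>	17	19	9
1	pchcms4	9.51	30.7	<abxab>	18	19	9
1	CPPCT045	32.02	77.5	<abxab>	7	30	9
2	ssrPaCITA19	13.01	0.0	<abxab>	18	18	10
2	UDP98-411	20.17	17.2	<abxab>	13	24	9
2	CPSCT021	23.74	36.9	<abxab>	10	27	9
2	CPSCT031	25.15	40.3	<abxab>	10	26	10
3	ssrPaCITA23	2.70	0.0	<abxab>	8	25	13
3	UDAp468	4.85	18.0	<abxab>	20	16	9
3	PGS3_03	16.41	44.7	<abxab>	5	20	21
3	EPPCU7190	19.78	69.0	<abxab>	18	25	2
4	UDP96-003	8.76	0.0	<abxab>	9	25	12
4	BPPCT040	6.46	12.0	<abxab>	10	27	9
4	UDAp404	-	25.4	<abxab>	12	26	8
5	PGS5_02	0.48	0.0	<abxab>	8	24	12
5	UDAp452	13.76	52.3	<abxab>	8	23	15
5	CPSCT006	11.53	95.1	<abxab>	10	25	11
6	PGS6_04	4.95	0.0	<abxab>	5	23	16
6	UDAp420	8.14	21.6	<abxab>	6	20	20
6	UDAp489	16.82	31.9	<abxab>	18	21	7
6	Ma027a	20.90	41.3	<abxab>	16	25	4
6	ssrPaCITA12	27.84	64.3	<abxab>	7	22	17
6	Locus-S	26.45	67.6	<abxab>	6	23	17
7	CPSCT026	10.98	0.0	<abxab>	13	23	10
7	CPPCT022	10.23	0.0	<abxab>	13	23	10
7	CPSCT042	17.08	29.2	<abxab>	10	20	16
8	PGS8_02	3.28	0.0	<abxab>	7	24	7
8	PGS8_05	7.39	3.4	<abxab>	8	25	11
8	UDAp401	10.50	7.2	<abxab>	10	23	12
8	UDAp470	12.61	7.2	<abxab>	10	24	12
8	M6a	15.03	11.8	<abxab>	9	25	11
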