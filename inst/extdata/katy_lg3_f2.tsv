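# High-density LG3 distortion scan, 'K x K' F2 population (87 trees)
locus	scaffold	position_mb	position_cm	seg_type	A	H	B
MA066a	scaffold_3	2.40	0.0	<abxab>	15	46	25
ssrPaCITA23	scaffold_3	2.70	2.3	<abxab>	16	44	27
UDAp468	scaffold_3	4.85	12.1	<abxab>	16	38	31
BPPCT039	scaffold_3	5.80	19.6	<abxab>	13	42	30
PGS3_03	scaffold_3	16.41	39.2	<abxab>	4	46	35
PGS3_12	scaffold_3	17.38	46.3	<abxab>	4	44	35
PGS3_15	scaffold_3	17.71	46.9	<abxab>	4	45	32
PGS3_22	scaffold_3	18.49	49.2	<abxab>	3	45	35
PGS3_23	scaffold_3	18.61	51.1	<abxab>	0	48	37
PGS3_28	scaffold_3	19.14	55.1	<abxab>	3	49	31
PGS3_32	scaffold_3	19.60	56.8	<abxab>	4	48	31
PGS3_33	scaffold_3	19.66	56.9	<abxab>	4	50	30
AMPA119	scaffold_3	20.00	59.0	<abxab>	4	47	35
EPPCU7190	scaffold_3	19.78	59.1	<abxab>	4	47	33
CPDCT027	scaffold_3	21.67	67.1	<abxab>	9	40	32
EPPCU0532	scaffold_3	22.00	72.0	<abxab>	12	42	21
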