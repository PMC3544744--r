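# LG3 distortion scan in 60 outcross seedlings (H x K, G x K, C x K) selected by
# S-genotype to carry the pollen-part mutation; transmitted-allele class counts
locus	scaffold	position_mb	populations	seg_type	c	d	e	g	n	p
MA066a	scaffold_3	2.40	HxK/GxK	<efxeg>/<nnxnp>	-	-	5	6	11	14
ssrPaCITA23	scaffold_3	2.70	HxK/GxK	<efxeg>	-	-	16	20	-	-
UDAp468	scaffold_3	4.85	HxK/CxK	<efxeg>	-	-	21	14	-	-
BPPCT039	scaffold_3	5.80	HxK/CxK	<abxcd>/<efxeg>	3	8	13	9	-	-
PGS3_03	scaffold_3	16.41	HxK/CxK	<efxeg>	-	-	33	2	-	-
PGS3_12	scaffold_3	17.38	all	<efxeg>/<nnxnp>	-	-	23	1	34	2
PGS3_15	scaffold_3	17.71	CxK	<efxeg>	-	-	24	0	-	-
PGS3_22	scaffold_3	18.49	all	<efxeg>/<nnxnp>	-	-	36	0	24	0
PGS3_23	scaffold_3	18.61	all	<efxeg>/<nnxnp>	-	-	36	0	24	0
PGS3_28	scaffold_3	19.14	all	<nnxnp>	-	-	-	-	60	0
PGS3_32	scaffold_3	19.60	all	<efxeg>/<nnxnp>	-	-	11	0	48	1
PGS3_33	scaffold_3	19.66	all	<abxcd>/<efxeg>	0	11	48	1	-	-
AMPA119	scaffold_3	20.00	all	<efxeg>	-	-	59	1	-	-
EPPCU7190	scaffold_3	19.78	all	<efxeg>	-	-	59	1	-	-
CPDCT027	scaffold_3	21.67	all	<abxcd>/<nnxnp>	31	3	-	-	19	5
EPPCU0532	scaffold_3	22.00	HxK/GxK	<efxeg>/<nnxnp>	-	-	11	0	21	3
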