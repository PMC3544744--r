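# F3 segregation counts for six F2 recombinants of the 'K x K' populations;
# f2_genotype is the F2's own call at the marker, A/H/B counts are the F3 embryos
f2_id	marker	f2_genotype	A	H	B
K05-12	PGS3_22	H	0	14	15
K05-24	PGS3_15	A	63	0	0
K05-24	PGS3_28	H	0	31	32
K06-05	PGS3_22	H	0	12	6
K06-06	PGS3_15	A	24	0	0
K06-06	PGS3_28	H	0	9	15
K06-17	PGS3_15	H	10	8	3
K06-17	PGS3_23	B	0	0	21
K06-21	PGS3_15	H	5	15	9
K06-21	PGS3_23	B	0	0	29
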