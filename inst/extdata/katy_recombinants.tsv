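# Graphical genotypes (typed markers only) of the six F3-tested F2 recombinants,
# as shown on the published graphical LG3 map. The PGS3_22 calls of K06-17 and
# K06-21 are reconstructed from the figure's breakpoint placement (the table
# itself leaves those two cells blank); see the package vignette.
f2_id	marker	position_mb	genotype
K05-12	PGS3_12	17.38	H
K05-12	PGS3_22	18.49	H
K05-12	EPPCU7190	19.78	B
K05-24	PGS3_12	17.38	A
K05-24	PGS3_15	17.71	A
K05-24	PGS3_28	19.14	H
K05-24	EPPCU7190	19.78	H
K06-05	PGS3_12	17.38	H
K06-05	PGS3_22	18.49	H
K06-05	EPPCU7190	19.78	H
K06-06	PGS3_12	17.38	A
K06-06	PGS3_15	17.71	A
K06-06	PGS3_28	19.14	H
K06-06	EPPCU7190	19.78	H
K06-17	PGS3_12	17.38	H
K06-17	PGS3_15	17.71	H
K06-17	PGS3_22	18.49	H
K06-17	PGS3_23	18.61	B
K06-17	EPPCU7190	19.78	B
K06-21	PGS3_12	17.38	H
K06-21	PGS3_15	17.71	H
K06-21	PGS3_22	18.49	H
K06-21	PGS3_23	18.61	B
K06-21	EPPCU7190	19.78	B
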