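# S-genotype counts of selfing and outcross progenies of the self-compatible apricot 'Katy'
# classes are listed in the published column order; ratio = expectation for a single
# heterozygous pollen-part mutation unlinked to the S-locus
cross	class	count	ratio
K x K	S1S2	45	2:1:1
K x K	S2S2	33	2:1:1
K x K	S1S1	16	2:1:1
G x K	S1S2	12	2:1:1
G x K	S2S2	10	2:1:1
G x K	S1S1	4	2:1:1
H x K	S1S2	20	2:1:1:2
H x K	S1S1	4	2:1:1:2
H x K	S1S4	7	2:1:1:2
H x K	S2S4	13	2:1:1:2
K x C	S1SC	15	2:2:1:1
K x C	S2SC	19	2:2:1:1
K x C	S1S2	6	2:2:1:1
K x C	S2S2	10	2:2:1:1
C x K	S1SC	32	2:1:2:1
C x K	S2SC	15	2:1:2:1
C x K	S1S2	29	2:1:2:1
C x K	S2S2	12	2:1:2:1
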