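gene	chrom	pos	protein_change	ref_allele	alt_allele	1-1	1-2	1-3	2-1	2-2
LPIN1	2	11919668	p.T249K	C	A	CA	CA	CA	CC	CA
STAB1	3	52556168	p.S2129R	C	G	CG	CG	CC	CC	CG
MSR1	8	16012594	p.R293X	C	T	CT	CT	CT	CT	CC
ABCC2	10	101594176	p.R1100S	C	A	CA	CC	CA	CC	CA
PGS1	17	76395566	p.G217S	G	A	GA	GG	GA	GA	GG
OSBPL1A	18	21957382	p.C39fs	-	AATT	-/AATT	-/-	-/-	-/AATT	-/-
MC4R	18	58038777	p.I269N	T	A	TA	TT	TT	TT	TA
LDLR	19	11215918	p.E113fs	-	G	G/G	-/G	G/G	-/G	-/G
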