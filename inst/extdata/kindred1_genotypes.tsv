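gene	chrom	pos	protein_change	ref_allele	alt_allele	1-1	1-2	1-3	1-4	1-6	2-1	2-2	2-3	2-5	3-1	3-2	3-3
APOB	2	21259976	p.G230V	G	T	GT	GT	GG	GG	GG	GG	GG	GT	GG	GG	GG	GT
MYL5	4	673778	p.F88S	T	C	TC	TT	TT	TT	TT	TT	TT	TC	TT	TT	TT	TT
MSR1	8	16001102	p.G333V	G	T	GT	GG	GG	GG	GG	GG	GT	GG	GG	GG	GT	GG
ABCA1	9	107589238	p.K776N	G	C	GC	GG	GG	GG	GG	GG	GG	GC	GG	GG	GG	GC
SPTY2D1	11	18637499	p.K107del	AGA	-	AGA/-	AGA/-	AGA/-	AGA/AGA	AGA/AGA	AGA/-	AGA/-	AGA/AGA	AGA/AGA	AGA/-	AGA/AGA	AGA/AGA
LCAT	16	67976320	p.S232T	T	A	TA	TA	TA	TT	TT	TT	TT	TA	TT	TT	TT	TT
PCTP	17	53844742	p.C63Y	G	A	GA	GA	GG	GG	GG	GG	GG	GA	GG	GG	GG	GG
LDLR	19	11198407	exon1_2977bp_del	-	del	-/del	-/del	-/del	-/-	-/-	-/-	-/-	-/del	-/-	-/-	-/-	-/del
LDLR	19	11227604	p.G592E	G	A	GA	GG	GG	GG	GG	GA	GA	GG	GG	GG	GA	GG
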