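Chromosome	Position	ID	Gene	Exon	cDNA	Protein	Consequence	Ref	Alt	Depth	Clinvar	GnomAD	TOPMED	ExAC	SIFT	Polyphen2_HDIV	Polyphen2_HVAR	LRT	MutationTaster	MutationAssessor	PROVEAN	FATHMM	MetaSVM_pred	GERP_RS	MetaSVM_score
2	21259976	.	APOB	exon6	c.G689T	p.G230V	missense	G	T	50	.	.	.	.	D	D	D	D	D	M	D	T	T	5.64	-0.4609
4	673778	rs2228354	MYL5	exon4	c.T263C	p.F88S	missense	T	C	50	Not reported	0.00665	0.00593	0.0069	D	D	D	U	D	H	D	D	D	4.12	0.7855
8	16001102	.	MSR1	exon8	c.G998T	p.G333V	missense	G	T	50	.	.	.	.	D	D	D	D	D	H	D	D	D	4.9	1.0032
9	107589238	rs138880920	ABCA1	exon16	c.G2328C	p.K776N	missense	G	C	50	Likely benign	0.0033	0.00198	0.0036	D	D	D	D	D	M	D	D	D	3.27	0.3243
11	18637499	rs66514853	SPTY2D1	exon3	c.320_322delAGA	p.K107del	nonframeshift_indel	AGA	-	50	Not reported	0.01726	0.01695	0.0169	.	.	.	.	.	.	.	.	.	.	.
16	67976320	rs4986970	LCAT	exon5	c.T694A	p.S232T	missense	T	A	50	.	0.01758	0.01669	0.01807	T	D	P	U	D	L	N	D	D	3.84	0.1186
17	53844742	rs112454522	PCTP	exon2	c.G188A	p.C63Y	missense	G	A	50	.	0.00473	0.00444	0.0049	D	D	D	D	D	M	D	T	T	5.64	-0.6575
19	11227604	rs137929307	LDLR	exon12	c.G1775A	p.G592E	missense	G	A	50	Pathogenic/Likely pathogenic	0.00004	0.00003	0.00005	D	D	D	D	D	M	D	D	D	5.48	1.0446
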