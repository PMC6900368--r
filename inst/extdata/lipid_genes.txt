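# Curated lipid-metabolism candidate genes (subset bundled for the
# worked examples; the full curated list of a study would be supplied by
# the user as one symbol per line).
LDLR
APOB
PCSK9
LDLRAP1
STAP1
CYP7A1
LIPA
ABCG5
ABCG8
ABCA1
LCAT
CETP
LPL
LIPC
APOE
APOA1
APOA5
APOC2
APOC3
LMF1
GPIHBP1
ANGPTL3
ANGPTL4
MTTP
SAR1B
SORT1
NPC1L1
SCARB1
MYL5
MSR1
SPTY2D1
PCTP
LPIN1
STAB1
ABCC2
PGS1
OSBPL1A
MC4R
KLF14
HMGCR
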