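FID	IID	FATHER	MOTHER	SEX	AGE	LDL	HDL
K2	2-1	0	0	M	35	266	56
K2	2-2	0	0	F	32	243	30
K2	1-1	2-1	2-2	F	2	672	20
K2	1-2	2-1	2-2	F	6	205	23
K2	1-3	2-1	2-2	F	1	791	25
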