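FID	IID	FATHER	MOTHER	SEX	AGE	LDL	HDL
K1	3-1	0	0	F	62	146	50
K1	3-2	0	0	M	65	393	81
K1	3-3	0	0	F	60	383	48
K1	3-4	0	0	M	66	NA	NA
K1	2-1	3-2	3-1	F	38	221	68
K1	2-2	3-2	3-1	F	36	192	62
K1	2-3	3-4	3-3	M	43	301	46
K1	2-5	0	0	M	40	130	32
K1	1-1	2-3	2-2	F	5	719	36
K1	1-2	2-3	2-2	F	10	315	42
K1	1-3	2-3	2-2	M	8	232	55
K1	1-4	2-5	2-1	M	12	102	56
K1	1-6	2-5	2-1	F	19	171	85
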