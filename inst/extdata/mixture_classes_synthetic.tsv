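# Synthetic CAT-like site class profiles (physicochemical classes); weights uniform. Not published CAT values.
weight	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
0.166666666666667	0.001	0.001	0.001	0.001	0.001	0.001	0.001	0.246	0.001	0.246	0.246	0.001	0.001	0.001	0.001	0.001	0.001	0.246	0.001	0.001
0.166666666666667	0.197	0.197	0.001	0.001	0.001	0.197	0.001	0.001	0.001	0.001	0.001	0.001	0.001	0.001	0.001	0.197	0.197	0.001	0.001	0.001
0.166666666666667	0.001	0.001	0.141	0.141	0.001	0.001	0.141	0.001	0.141	0.001	0.001	0.141	0.001	0.141	0.141	0.001	0.001	0.001	0.001	0.001
0.166666666666667	0.001	0.001	0.001	0.001	0.246	0.001	0.246	0.001	0.001	0.001	0.001	0.001	0.001	0.001	0.001	0.001	0.001	0.001	0.246	0.246
0.166666666666667	0.001	0.001	0.246	0.001	0.001	0.001	0.001	0.001	0.001	0.001	0.001	0.246	0.001	0.001	0.001	0.246	0.246	0.001	0.001	0.001
0.166666666666667	0.001	0.001	0.197	0.001	0.001	0.197	0.001	0.001	0.001	0.001	0.001	0.197	0.197	0.001	0.001	0.197	0.001	0.001	0.001	0.001
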