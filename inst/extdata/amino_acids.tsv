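aa	letter	vdw_volume	pka	logp	mol_weight	sc_c	sc_n	sc_o	sc_s	sc_benzene	bb_ia	bb_iva	polar_requirement	aa_class	aars_class	transfer_weight
Ala	A	67	7.00	-2.85	89.09	1	0	0	0	0	1	0	7.0	simple	II	8.25
Arg	R	148	12.48	-4.20	174.20	1	1	0	0	0	1	0	9.1	complex	I	5.53
Asn	N	96	7.00	-3.82	132.12	1	1	1	0	0	1	0	10.0	complex	II	4.06
Asp	D	91	3.65	-3.89	133.10	1	0	1	0	0	1	0	13.0	simple	II	5.45
Cys	C	86	8.28	-2.49	121.16	1	0	0	1	0	1	0	4.8	sulfur	I	1.37
Gln	Q	114	7.00	-3.64	146.15	1	1	1	0	0	1	0	8.6	complex	I	3.93
Glu	E	109	4.25	-3.69	147.13	1	0	1	0	0	1	0	12.5	simple	I	6.75
Gly	G	48	7.00	-3.21	75.07	0	0	0	0	0	1	0	7.9	simple	II	7.07
His	H	118	6.00	-3.32	155.16	1	1	0	0	0	1	0	8.4	complex	II	2.27
Ile	I	124	7.00	-1.70	131.17	1	0	0	0	0	1	0	4.9	simple	I	5.96
Leu	L	124	7.00	-1.52	131.17	1	0	0	0	0	1	0	4.9	simple	I	9.66
Lys	K	135	10.53	-3.05	146.19	1	1	0	0	0	1	0	10.1	complex	II	5.84
Met	M	124	7.00	-1.87	149.21	1	0	0	1	0	1	0	5.3	sulfur	I	2.42
Phe	F	135	7.00	-1.38	165.19	1	0	0	0	1	1	0	5.0	complex	II	3.86
Pro	P	90	7.00	-2.54	115.13	1	0	0	0	0	0	1	6.6	simple	II	4.70
Ser	S	73	7.00	-3.07	105.09	1	0	1	0	0	1	0	7.5	simple	II	6.56
Thr	T	93	7.00	-2.94	119.12	1	0	1	0	0	1	0	6.6	simple	II	5.34
Trp	W	163	7.00	-1.05	204.23	1	1	0	0	1	1	0	5.2	complex	I	1.08
Tyr	Y	141	10.07	-2.26	181.19	1	0	1	0	1	1	0	5.4	complex	I	2.92
Val	V	105	7.00	-2.26	117.15	1	0	0	0	0	1	0	5.6	simple	I	6.87
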