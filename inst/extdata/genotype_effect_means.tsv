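chrom	pos	gene	genotype	area_high	width_high	area_low	width_low	diff_area	diff_width
1	22082784	CIPK3	GG	1.677	1.107	1.598	1.054	4.96	5.05
1	28403445	SAG101	AG	1.760	1.169	1.644	1.085	7.04	7.72
1	43033561	CRPK1	AG	1.66	1.104	1.585	1.044	5.27	5.69
2	9660163	AR781	TT	1.750	1.169	1.625	1.070	7.75	9.30
2	6092252	DIS3L2	GG	1.823	1.212	1.598	1.051	14.08	15.33
4	22733081	LRR_kinase	TC	1.723	1.136	1.547	1.014	11.38	12.09
12	14701685	LAP1	CC	1.656	1.096	1.601	1.057	3.43	3.72
14	5416939	COP11	AT	1.733	1.138	1.644	1.084	5.39	4.92
15	4747203	PIN1	GG	1.468	0.964	1.610	1.075	9.64	11.46
15	8379891	CDK-like	TT	1.475	0.970	1.530	1.007	3.75	3.90
18	9890878	CAK1AT	TT	1.682	1.117	1.611	1.065	4.41	4.89
379	2531	Stress-antifung	TC	1.701	1.129	1.615	1.069	5.33	5.64
1	36327299	NAP5	TT	1.610	1.059	1.478	0.954	8.93	11.03
1	35770384	JMT	CC	1.619	1.063	1.444	0.942	12.05	12.90
2	21186580	BHLH76	TT	1.656	1.096	1.455	0.942	13.84	16.38
2	9487450	Protein_kinase	GG	1.656	1.096	1.455	0.942	13.84	16.38
3	18093953	IIB	GG	1.581	1.044	1.506	0.987	4.94	5.79
5	20022064	SCL1	CT	1.642	1.081	1.564	1.031	4.97	4.86
6	10067699	EIN2	AG	1.596	1.049	1.542	1.011	3.51	3.79
7	152674	IIIC63	TT	1.620	1.069	1.551	1.023	4.43	4.46
10	11244085	Remorin	AA	1.609	1.058	1.402	0.902	14.74	17.28
11	17887288	JMJ18	GG	1.633	1.080	1.523	0.999	7.22	8.03
16	13960977	PIN-LIKES	GG	1.642	1.086	1.517	1.001	8.23	8.48
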