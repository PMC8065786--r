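index	name	abbrev	hemisphere
1	Left frontal pole	FP.L	L
2	Right frontal pole	FP.R	R
3	Left superior frontal gyrus	SFG.L	L
4	Right superior frontal gyrus	SFG.R	R
5	Left middle frontal gyrus	MFG.L	L
6	Right middle frontal gyrus	MFG.R	R
7	Left precentral gyrus	PrG.L	L
8	Right precentral gyrus	PrG.R	R
9	Left opercular part of the inferior frontal gyrus	OpIFG.L	L
10	Right opercular part of the inferior frontal gyrus	OpIFG.R	R
11	Left triangular part of the inferior frontal gyrus	TrIFG.L	L
12	Right triangular part of the inferior frontal gyrus	TrIFG.R	R
13	Left orbital part of the inferior frontal gyrus	OrIFG.L	L
14	Right orbital part of the inferior frontal gyrus	OrIFG.R	R
15	Left anterior orbital gyrus	AOrG.L	L
16	Right anterior orbital gyrus	AOrG.R	R
17	Left lateral orbital gyrus	LOrG.L	L
18	Right lateral orbital gyrus	LOrG.R	R
19	Left medial orbital gyrus	MOrG.L	L
20	Right medial orbital gyrus	MOrG.R	R
21	Left posterior orbital gyrus	POrG.L	L
22	Right posterior orbital gyrus	POrG.R	R
23	Left gyrus rectus	GRe.L	L
24	Right gyrus rectus	GRe.R	R
25	Left medial frontal cortex	MFC.L	L
26	Right medial frontal cortex	MFC.R	R
27	Left supplementary motor cortex	SMC.L	L
28	Right supplementary motor cortex	SMC.R	R
29	Left medial superior frontal gyrus	MSFG.L	L
30	Right medial superior frontal gyrus	MSFG.R	R
31	Left subcallosal area	SCA.L	L
32	Right subcallosal area	SCA.R	R
33	Left central operculum	CO.L	L
34	Right central operculum	CO.R	R
35	Left frontal operculum	FO.L	L
36	Right frontal operculum	FO.R	R
37	Left anterior insula	AIns.L	L
38	Right anterior insula	AIns.R	R
39	Left posterior insula	PIns.L	L
40	Right posterior insula	PIns.R	R
41	Left anterior cingulate gyrus	ACgG.L	L
42	Right anterior cingulate gyrus	ACgG.R	R
43	Left middle cingulate gyrus	MCG.L	L
44	Right middle cingulate gyrus	MCG.R	R
45	Left posterior cingulate gyrus	PCgG.L	L
46	Right posterior cingulate gyrus	PCgG.R	R
47	Left postcentral gyrus	PcG.L	L
48	Right postcentral gyrus	PcG.R	R
49	Left superior parietal lobule	SPL.L	L
50	Right superior parietal lobule	SPL.R	R
51	Left supramarginal gyrus	SMG.L	L
52	Right supramarginal gyrus	SMG.R	R
53	Left angular gyrus	AnG.L	L
54	Right angular gyrus	AnG.R	R
55	Left precuneus	Pcun.L	L
56	Right precuneus	Pcun.R	R
57	Left parietal operculum	PO.L	L
58	Right parietal operculum	PO.R	R
59	Left superior occipital gyrus	SOG.L	L
60	Right superior occipital gyrus	SOG.R	R
61	Left middle occipital gyrus	MOG.L	L
62	Right middle occipital gyrus	MOG.R	R
63	Left inferior occipital gyrus	IOG.L	L
64	Right inferior occipital gyrus	IOG.R	R
65	Left occipital pole	OP.L	L
66	Right occipital pole	OP.R	R
67	Left calcarine cortex	Calc.L	L
68	Right calcarine cortex	Calc.R	R
69	Left cuneus	Cun.L	L
70	Right cuneus	Cun.R	R
71	Left lingual gyrus	LiG.L	L
72	Right lingual gyrus	LiG.R	R
73	Left occipital fusiform gyrus	OFuG.L	L
74	Right occipital fusiform gyrus	OFuG.R	R
75	Left superior temporal gyrus	STG.L	L
76	Right superior temporal gyrus	STG.R	R
77	Left middle temporal gyrus	MTG.L	L
78	Right middle temporal gyrus	MTG.R	R
79	Left inferior temporal gyrus	ITG.L	L
80	Right inferior temporal gyrus	ITG.R	R
81	Left temporal pole	TP.L	L
82	Right temporal pole	TP.R	R
83	Left planum temporale	PT.L	L
84	Right planum temporale	PT.R	R
85	Left planum polare	PP.L	L
86	Right planum polare	PP.R	R
87	Left transverse temporal gyrus	TTG.L	L
88	Right transverse temporal gyrus	TTG.R	R
89	Left fusiform gyrus	FuG.L	L
90	Right fusiform gyrus	FuG.R	R
91	Left parahippocampal gyrus	PhG.L	L
92	Right parahippocampal gyrus	PhG.R	R
93	Left entorhinal area	Ent.L	L
94	Right entorhinal area	Ent.R	R
95	Left hippocampus	Hi.L	L
96	Right hippocampus	Hi.R	R
97	Left amygdala	Amg.L	L
98	Right amygdala	Amg.R	R
99	Left caudate nucleus	CN.L	L
100	Right caudate nucleus	CN.R	R
101	Left putamen	Pu.L	L
102	Right putamen	Pu.R	R
103	Left pallidum	Pd.L	L
104	Right pallidum	Pd.R	R
105	Left thalamus	Th.L	L
106	Right thalamus	Th.R	R
107	Left ventral diencephalon	VDc.L	L
108	Right ventral diencephalon	VDc.R	R
109	Left nucleus accumbens	NAc.L	L
110	Right nucleus accumbens	NAc.R	R
111	Left cerebellum exterior	CbE.L	L
112	Right cerebellum exterior	CbE.R	R
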