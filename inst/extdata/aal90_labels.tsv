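index	abbrev	class
1	PreCG.L	Primary
2	PreCG.R	Primary
3	SFGdor.L	Association
4	SFGdor.R	Association
5	ORBsup.L	Paralimbic
6	ORBsup.R	Paralimbic
7	MFG.L	Association
8	MFG.R	Association
9	ORBmid.L	Paralimbic
10	ORBmid.R	Paralimbic
11	IFGoperc.L	Association
12	IFGoperc.R	Association
13	IFGtriang.L	Association
14	IFGtriang.R	Association
15	ORBinf.L	Paralimbic
16	ORBinf.R	Paralimbic
17	ROL.L	Primary
18	ROL.R	Primary
19	SMA.L	Association
20	SMA.R	Association
21	OLF.L	Paralimbic
22	OLF.R	Paralimbic
23	SFGmed.L	Association
24	SFGmed.R	Association
25	ORBsupmed.L	Paralimbic
26	ORBsupmed.R	Paralimbic
27	REC.L	Paralimbic
28	REC.R	Paralimbic
29	INS.L	Paralimbic
30	INS.R	Paralimbic
31	ACG.L	Paralimbic
32	ACG.R	Paralimbic
33	DCG.L	Paralimbic
34	DCG.R	Paralimbic
35	PCG.L	Paralimbic
36	PCG.R	Paralimbic
37	HIP.L	Limbic
38	HIP.R	Limbic
39	PHG.L	Limbic
40	PHG.R	Limbic
41	AMYG.L	Limbic
42	AMYG.R	Limbic
43	CAL.L	Primary
44	CAL.R	Primary
45	CUN.L	Association
46	CUN.R	Association
47	LING.L	Association
48	LING.R	Association
49	SOG.L	Association
50	SOG.R	Association
51	MOG.L	Association
52	MOG.R	Association
53	IOG.L	Association
54	IOG.R	Association
55	FFG.L	Association
56	FFG.R	Association
57	PoCG.L	Primary
58	PoCG.R	Primary
59	SPG.L	Association
60	SPG.R	Association
61	IPL.L	Association
62	IPL.R	Association
63	SMG.L	Association
64	SMG.R	Association
65	ANG.L	Association
66	ANG.R	Association
67	PCUN.L	Association
68	PCUN.R	Association
69	PCL.L	Primary
70	PCL.R	Primary
71	CAU.L	Subcortical
72	CAU.R	Subcortical
73	PUT.L	Subcortical
74	PUT.R	Subcortical
75	PAL.L	Subcortical
76	PAL.R	Subcortical
77	THA.L	Subcortical
78	THA.R	Subcortical
79	HES.L	Primary
80	HES.R	Primary
81	STG.L	Association
82	STG.R	Association
83	TPOsup.L	Paralimbic
84	TPOsup.R	Paralimbic
85	MTG.L	Association
86	MTG.R	Association
87	TPOmid.L	Paralimbic
88	TPOmid.R	Paralimbic
89	ITG.L	Association
90	ITG.R	Association
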