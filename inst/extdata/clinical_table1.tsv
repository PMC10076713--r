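patient_id	gender	age	diagnosis	treatment	recist	biopsy_site	prior_treatments
1	female	64	PAAD	Atezolizumab + Cergutuzumab Amunaleukin	PD	Liver	2
2	female	62	BRCA	Atezolizumab	PD	Liver	6
3	female	28	COAD	Atezolizumab + Cergutuzumab Amunaleukin	PD	Lung	3
4	female	46	READ	Atezolizumab + Cergutuzumab Amunaleukin	PD	Liver	3
5	female	42	CESC	Atezolizumab + Selicrelumab	PD	Lymph node	6
6	male	70	PAAD	Atezolizumab + Cergutuzumab Amunaleukin	PD	Lung	2
7	female	50	CCA-IG	Ipilimumab + Nivolumab	PD	Peritoneum	4
8	female	51	SKCN	Pembrolizumab	PD	Liver	3
9	female	43	BRCA	Pembrolizumab	PD	Lymph node	6
10	male	71	COAD	Nivolumab	PD	Primary tumor	2
11	male	70	BLCA	Pembrolizumab	PD	Peritoneum	2
12	female	47	BRCA	Atezolizumab + Selicrelumab	PD	Liver	6
13	male	61	UC-U	Pembrolizumab	SD	Liver	2
14	female	38	CESC	Pembrolizumab	PR	Lymph node	4
15	female	53	CDC-K	Nivolumab	PR	Kidney	1
16	female	71	BRCA	Atezolizumab	SD	Subcutaneous/Cutaneous	7
17	female	56	BLCA	Atezolizumab + Selicrelumab	SD	Other	2
18	female	70	BLCA	Ipilimumab + Nivolumab	PR	Lymphnode	2
19	male	64	BLCA	Ipilimumab + Nivolumab	CR	Lymphnode	2
20	male	42	COAD	Pembrolizumab	PD	Subcutaneous/Cutaneous	3
21	male	74	LIHC	Nivolumab + Relatlimab	CR	Liver	2
22	male	61	BLCA	Pembrolizumab	PR	Lymph node	1
23	male	73	READ	Atezolizumab + Cibisatamab	PD	Liver	3
24	female	63	OV	Atezolizumab + BET inhibitor	PD	Subcutaneous	6
25	female	41	BRCA	Chemotherapy + Pembrolizumab	PR	Lymph node	3
26	female	42	BRCA	Chemotherapy + Pembrolizumab	PD	Lymph node	1
27	female	56	COAD	Atezolizumab + Cibisatamab	PD	Liver	2
28	female	49	OV	Atezolizumab + BET inhibitor	SD	Lymph node	3
29	male	67	READ	Atezolizumab + Selicrelumab	PD	Liver	4
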