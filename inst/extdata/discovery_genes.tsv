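gene	chrom	case_id	mode	clinical_cvm	clinical_noncvm	support	op_percentile	pli
ACVR1	2	LO1462	De novo	0	0	MGI,HE,TGFB	0.201	0.96
JARID2	6	LO0189	De novo	1	0	MGI,PITX2	0	0.99
KMT2D	12	LO0785	De novo	7	13	CVM	0	1
NF1	17	LO2000	De novo	1	4	CVM,MGI,HE	0.166	1
NR2F2	15	LO0260	De novo	0	0	CVM,MGI	0	0.91
PLRG1	4	LO0943	De novo	0	0	MGI	0	0.99
SMURF1	7	LO1765	De novo	1	0	TGFB	0	0.99
TBX20	7	LO0746	De novo	0	0	CVM,MGI,HE	0	0.34
ZEB2	2	LO0747	De novo	6	4	CVM,ZFIN	0	0.99
ARHGEF11	1	LO2218	Inherited	2	0	ZFIN	0.156	0.99
CCDC91	12	LO0222	Inherited	1	3	PITX2	0	3.2E-05
CDH2	18	LO1263	Inherited	2	2	MGI,HE,PITX2	0.077	1
E2F6	2	LO0970	Inherited	0	0	PITX2	0	0.55
FGF19	11	LO1957	Inherited	0	0	MGI	0	0.29
GJC1	17	LO0192	Inherited	0	0	MGI,ZFIN	0	0.94
GLRX3	10	LO0350	Inherited	0	0	MGI,HE	0	0.63
LATS2	13	LO0238	Inherited	2	4	MGI	0.119	0.87
LTBP1	2	LO2218	Inherited	1	2	MGI,TGFB	0	0.53
MNDA	1	LO0369	Inherited	0	0	CHD_candidate	0.265	7.2E-11
PCDHGA2	5	LO0605	Inherited	0	4	HE	0	8.2E-07
PCSK6	15	LO1210	Inherited	2	3	MGI	0	0.01
RAC1	7	LO0938	Inherited	0	0	MGI,HE	0	0.57
DNAH5	5	LO1298	Recessive	6	30	CVM,MGI,HE,PCD	0.299	5.8E-37
OFD1	X	LO1488	X-linked	1	3	CVM,MGI,ZFIN	0	0.98
BMP1	8	LO0605	Unknown	0	1	MGI	0	0.87
JMJD6	17	LO0295	Unknown	0	1	MGI	0	0.82
ROCK1	18	LO0453	Unknown	1	5	MGI,TGFB,PITX2	0	1
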