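#variant	gene	enrichment_or	study_af	max_ref_af
16:3293310:A:G	MEFV	26.08	0.0416	0.0017
5:150723155:C:A	SLC36A2	3.51	0.0414	0.0122
1:155205634:T:C	GBA	11.16	0.0296	0.0027
4:187201412:T:C	F11	47.17	0.0273	0.0006
13:20763553:CA:C	GJB2	39.19	0.0199	0.0005
4:187195347:G:T	F11	28.20	0.0195	0.0007
12:14421038:G:A	PRB3	16.12	0.0189	0.0012
9:111662096:A:G	IKBKAP	45.22	0.0168	0.0004
15:72638920:G:GGATA	HEXA	19.14	0.0122	0.00064
1:125848678:C:T	USH2A	13.63	0.0106	0.0008
22:29091207:G:A	CHEX2	50.06	0.0103	0.0002
10:99371368:TGAG:T	HOGA1	29.28	0.0101	0.0003
7:117282620:G:A	CFTR	23.64	0.0085	0.0004
11:17418602:C:T	ABCC8	40.62	0.0076	0.0002
17:3402294:A:C	ASPA	40.36	0.0076	0.0002
2:98986540:G:A	CNGA3	26.11	0.0074	0.0003
13:32914437:GT:G	BRCA2	27.57	0.0069	0.0003
9:97934315:T:A	FANCC	42.75	0.0069	0.0002
9:108382330:G:GA	FKTN	32.62	0.0067	0.0002
12:40734202:G:A	LRRK2	20.64	0.0064	0.0003
17:41055964:C:T	G6PC	11.04	0.0062	0.0006
1:26764719:A:G	DHDDS	64.83	0.0051	0.0001
3:150690352:A:C	CLRN1	46.26	0.0051	0.0001
12:49312533:GTA:G	CCDC65	25.75	0.0048	0.0002
6:80878662:G:C	BCKDHB	29.42	0.0046	0.0002
10:56077147:G:A	PCDH15	26.58	0.0046	0.0002
7:107555951:G:T	DLD	26.55	0.0046	0.0002
15:72638575:C:G	HEXA	52.65	0.0044	0.0001
15:72105913:G:A	NR2E3	9.86	0.0042	0.0004
5:178699927:G:A	ADAMTS2	129.41	0.0041	0.0000
16:50745656:G:A	NOD2	12.48	0.0039	0.0003
11:6415434:G:T	SMPD1	41.53	0.0039	0.0001
11:61161437:G:T	THEM216	27.77	0.0039	0.0001
1:53676583:CAG:C	CPT2	78.34	0.0037	0.0000
1:53676688:T:C	CPT2	78.35	0.0037	0.0000
3:172737276:C:T	SPATA16	9.79	0.0037	0.0004
11:86017416:G:C	C11orf73	47.03	0.0037	0.0001
8:77896070:G:A	PEX2	20.03	0.0034	0.0002
11:118951899:T:G	VPS11	190.98	0.0030	0.0000
6:80203353:G:A	LCA5	29.25	0.0028	0.0001
19:7591645:A:G	MCOLN1	21.93	0.0028	0.0001
16:56530894:C:G	BBS2	29.37	0.0028	0.0001
17:41276044:ACT:A	BRCA1	10.04	0.0025	0.0003
4:100543913:G:T	MTTP	40.38	0.0025	0.0001
2:99013302:G:A	CNGA3	29.36	0.0023	0.0001
7:107557794:G:A	DLD	26.44	0.0021	0.0001
17:41209079:T:TG	BRCA1	8.80	0.0021	0.0002
10:99371292:G:T	HOGA1	22.01	0.0021	0.0001
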