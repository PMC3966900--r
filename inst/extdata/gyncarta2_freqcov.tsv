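# Catalogue mutation frequency fractions (occurrences/tested) and panel
# coverage percentages per gene and tissue for the packaged panel, as
# published for the four-tissue study and the pooled cohort ("all").
# coverage_pct is NA where coverage was not applicable (no catalogued
# occurrences in that tissue).
gene	tissue	occurrences	tested	coverage_pct
BRAF	cervix	6	434	0
BRAF	endometrium	33	2254	26
BRAF	ovary	253	3398	95
BRAF	all	292	6086	86
CDKN2A	cervix	23	248	8
CDKN2A	endometrium	13	427	33
CDKN2A	ovary	63	1378	13
CDKN2A	vulva	1	27	100
CDKN2A	all	100	2080	16
CTNNB1	cervix	7	130	57
CTNNB1	endometrium	283	1309	91
CTNNB1	ovary	105	1521	86
CTNNB1	all	395	2960	88
FBXW7	cervix	1	12	0
FBXW7	endometrium	33	307	22
FBXW7	ovary	6	882	33
FBXW7	all	40	1201	27
FGFR2	cervix	2	58	0
FGFR2	endometrium	88	927	77
FGFR2	ovary	4	857	50
FGFR2	all	94	1842	71
FGFR3	cervix	6	414	83
FGFR3	endometrium	2	262	0
FGFR3	ovary	0	792	NA
FGFR3	all	8	1468	83
FOXL2	cervix	0	28	NA
FOXL2	endometrium	0	216	NA
FOXL2	ovary	329	1794	100
FOXL2	all	329	2038	100
HRAS	cervix	15	215	87
HRAS	endometrium	0	528	NA
HRAS	ovary	0	731	NA
HRAS	vulva	0	13	NA
HRAS	all	15	2487	87
KRAS	cervix	45	617	100
KRAS	endometrium	327	2578	99
KRAS	ovary	522	4203	99
KRAS	vulva	0	14	NA
KRAS	all	894	7412	99
NRAS	cervix	2	127	100
NRAS	endometrium	11	548	100
NRAS	ovary	3	780	100
NRAS	vulva	0	13	NA
NRAS	all	16	1468	100
PIK3CA	cervix	39	332	94
PIK3CA	endometrium	562	2550	70
PIK3CA	ovary	198	2366	85
PIK3CA	all	799	5250	76
PPP2R1A	cervix	2	14	0
PPP2R1A	endometrium	76	645	72
PPP2R1A	ovary	36	1354	84
PPP2R1A	all	114	2013	75
PTEN	cervix	20	406	29
PTEN	endometrium	824	2170	40
PTEN	ovary	53	1487	40
PTEN	vulva	5	8	54
PTEN	all	906	4078	40
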