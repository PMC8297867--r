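insertion	identity	length	mt_start	mt_end	plastid_genes	evalue	bit_score
1	92.796	2707	388082	390750	None	0	3847
2	92.737	1308	390781	392071	None	0	1855
3	89.939	1471	110970	112426	ycf3*	0	1851
4	95.951	1062	393537	394582	atpB*	0	1709
5	84.731	1670	112464	114041	ycf3*-trnS	0	1561
6	88.306	1334	203429	204727	psbA*	0	1554
7	97.308	743	395525	396259	rbcL*	0	1254
8	95.979	746	392139	392872	atpE*-atpB*	0	1201
9	98.353	607	392902	393508	atpB*	0	1064
10	91.871	775	387315	388082	ndhC*	0	1059
11	97.373	609	394883	395491	rbcL*	0	1035
12	87.262	683	205250	205928	matK*	0	754
13	87.884	553	114933	115459	None	6.60E-176	617
14	88.024	501	202625	203116	trnHGUG	3.14E-159	562
15	88.475	295	204916	205204	trnKUUU*	1.60E-92	340
16	97.674	172	394651	394822	rbcL*	3.51E-79	296
17	85.507	207	114716	114915	None	6.09E-52	206
18	93.636	110	205988	206097	matK*	1.03E-39	165
19	86.885	122	203240	203361	psbA*	2.91E-30	134
20	94.118	85	255735	255819	trnMCAU	3.77E-29	130
21	94.595	74	391862	391793	trnMCAU	3.80E-24	113
22	91.935	62	25479	25539	trnMCAU*	8.28E-16	86.1
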