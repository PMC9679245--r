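population	code	region	latitude	longitude	n_collected	n_genotyped	he	ho	fis
Arcadia	ARCA	NA	44.49754	-86.2649	2	0	NA	NA	NA
Big Bay de Noc	BBDN	Northwest	45.77378	-86.7038	115	90	0.124	0.146	-0.049
Cross Village	CXVL	Northeast and East	45.64815	-85.0439	50	49	0.122	0.144	-0.048
Elk Rapids	EKRP	East	44.89042	-85.4592	34	23	0.117	0.144	-0.054
Epoufette	EPFT	Northeast and East	46.03675	-85.1758	48	48	0.119	0.146	-0.06
Fox River	FOXR	Northwest	44.54018	-88.0037	98	94	0.127	0.148	-0.046
Good Harbor Bay	GOOD	East	45.0486	-85.8689	23	19	0.118	0.146	-0.055
Ingalls Point	IGPT	East	45.07346	-85.5644	48	38	0.129	0.161	-0.072
Larson's Reef	LSRF	Northwest	44.89017	-87.4824	48	43	0.134	0.177	-0.101
Little Traverse Bay	LTTV	Northeast and East	45.40268	-85.0091	14	11	0.122	0.163	-0.074
Ludington	LUDI	NA	43.95548	-86.4893	1	0	NA	NA	NA
Manistique	MNST	Northwest	45.93338	-86.2383	48	42	0.127	0.16	-0.076
Menominee River	MENO	Northwest	45.09851	-87.6107	130	122	0.125	0.148	-0.051
Muskegon	MSKG	East	43.21106	-86.3435	50	33	0.119	0.154	-0.076
Naubinway	MAUB	Northeast and East	46.07598	-85.4492	40	37	0.123	0.153	-0.067
North/Moonlight Bays	NMNL	Northwest	45.10253	-87.049	125	104	0.123	0.15	-0.063
Peshtigo River	PSTG	Northwest	44.97299	-87.654	10	9	0.127	0.167	-0.067
Rileys Bay	RILY	Northwest	44.86496	-87.5275	17	17	0.13	0.17	-0.081
Whitefish Bay	WTFB	Northwest	44.90512	-87.1999	50	50	0.125	0.146	-0.046
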