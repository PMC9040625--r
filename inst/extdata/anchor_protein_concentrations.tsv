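protein_id	name	condition	mean	sd	n_peptides	status
CAETHG_RS00440	AOR1	CO	270	15	16	quantified
CAETHG_RS00440	AOR1	syngas	211	19	16	quantified
CAETHG_RS00440	AOR1	highH2CO	290	61	16	quantified
CAETHG_RS00580	IlvC	CO	186	8	7	quantified
CAETHG_RS00580	IlvC	syngas	196	27	7	quantified
CAETHG_RS00580	IlvC	highH2CO	190	42	7	quantified
CAETHG_RS00590	IlvB3	CO	13	1	2	quantified
CAETHG_RS00590	IlvB3	syngas	7	1	2	quantified
CAETHG_RS00590	IlvB3	highH2CO	104	26	2	quantified
CAETHG_RS02630	Adh3	CO	18	4	2	quantified
CAETHG_RS02630	Adh3	syngas	8	2	2	quantified
CAETHG_RS02630	Adh3	highH2CO	2	0.1	2	quantified
CAETHG_RS07815	AcsD	CO	633	44	7	quantified
CAETHG_RS07815	AcsD	syngas	509	41	7	quantified
CAETHG_RS07815	AcsD	highH2CO	703	40	7	quantified
CAETHG_RS07830	MetF	CO	254	16	5	quantified
CAETHG_RS07830	MetF	syngas	233	16	5	quantified
CAETHG_RS07830	MetF	highH2CO	280	36	5	quantified
CAETHG_RS07840	FolD	CO	114	4	4	quantified
CAETHG_RS07840	FolD	syngas	103	10	4	quantified
CAETHG_RS07840	FolD	highH2CO			4	NQ
CAETHG_RS07845	FchA	CO	308	30	2	quantified
CAETHG_RS07845	FchA	syngas	221	7	2	quantified
CAETHG_RS07845	FchA	highH2CO	313	68	2	quantified
CAETHG_RS07850	Fhs	CO	953	109	13	quantified
CAETHG_RS07850	Fhs	syngas	707	49	13	quantified
CAETHG_RS07850	Fhs	highH2CO	1122	107	13	quantified
CAETHG_RS07861	AcsA	CO	122	32	1	quantified
CAETHG_RS07861	AcsA	syngas	119	21	1	quantified
CAETHG_RS07861	AcsA	highH2CO	145	37	1	quantified
CAETHG_RS09495	RplA	CO	88	1	2	quantified
CAETHG_RS09495	RplA	syngas	103	12	2	quantified
CAETHG_RS09495	RplA	highH2CO	79	12	2	quantified
CAETHG_RS13725	FdhA	CO	62	4	9	quantified
CAETHG_RS13725	FdhA	syngas	41	5	9	quantified
CAETHG_RS13725	FdhA	highH2CO			9	NQ
CAETHG_RS13765	HytA	CO	72	1	8	quantified
CAETHG_RS13765	HytA	syngas	55	6	8	quantified
CAETHG_RS13765	HytA	highH2CO	94	20	8	quantified
CAETHG_RS14890	PFOR	CO	133	7	19	quantified
CAETHG_RS14890	PFOR	syngas	178	13	19	quantified
CAETHG_RS14890	PFOR	highH2CO	45	9	19	quantified
CAETHG_RS16490	Pta	CO	81	4	6	quantified
CAETHG_RS16490	Pta	syngas	89	4	6	quantified
CAETHG_RS16490	Pta	highH2CO	81	4	6	quantified
CAETHG_RS16495	AckA	CO	58	1	3	quantified
CAETHG_RS16495	AckA	syngas	71	8	3	quantified
CAETHG_RS16495	AckA	highH2CO	51	6	3	quantified
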