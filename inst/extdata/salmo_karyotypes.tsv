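basin	species_or_form	taxon_flag	locality	country	n_individuals	individuals_flag	two_n	m_sm	st_a	nf	reference	notes
Aral Sea Basin	S. oxianus		Kyzylsu R. (Amu Darya basin)	KAZ	3		80	18	62	98	53	1; 2
Aral Sea Basin	S. oxianus		Alamedin R. (Chu basin)	KG	5		80	18	62	98	53	1; 2
Aral Sea Basin	S. oxianus		Bech-Tach (Talas basin)	KG	11		80	18	62	98	53	1; 2
Balkans and Mediterranean Sea Basin	S. carpio		Garda L.	IT	embryos		80	20	60	100	54	1
Balkans and Mediterranean Sea Basin	S. cenerinus		Monti Sibillini	IT	57	†	80	14/8	58	102	55	2; 5
Balkans and Mediterranean Sea Basin	S. farioides		Drosopigi R.	GR	/		80	20	60	100	56	1; 2
Balkans and Mediterranean Sea Basin	S. lourosensis		Louros R.	GR	/		80	20	60	100	56	1; 2
Balkans and Mediterranean Sea Basin	S. letnica		Ochrid L.	MK	embryos		80			104	57	1
Balkans and Mediterranean Sea Basin	S. marmoratus		Socha R.	SI	/		80	22	58	102	58	1
Balkans and Mediterranean Sea Basin	S. marmoratus		Socha R.	SI	1		80	22	58	102	59	1
Balkans and Mediterranean Sea Basin	S. marmoratus		Idrijca R.	SI	2		80	22	58	102	59	1
Balkans and Mediterranean Sea Basin	S. marmoratus		Friuli-Venezia	IT	57	†	80	14/8	58	102	55	2; 5
Balkans and Mediterranean Sea Basin	S. obtusirostris		Buna R. (Neretva R. basin)	BIH	/		82	12	70	94	60	1
Balkans and Mediterranean Sea Basin	S. peristericus		Aigos Germanos	GR	/		80	20	60	100	56	1; 2
Balkans and Mediterranean Sea Basin	S. trutta	*	Buni, Krupica, Bistrica R.	RU	17		80	18-20	62-60	100	61	1; 2
Balkans and Mediterranean Sea Basin	S. trutta	*	Klinje L.	BIH	17		80	20	60	100	61	1; 2
Balkans and Mediterranean Sea Basin	S. trutta	*	Pschata R.	SI	/		80	20	60	100	58	1
Balkans and Mediterranean Sea Basin	S. trutta	*	Tripotamos R.	GR	/		76	16	60	92	56	1; 2
Baltic Sea Basin	S. trutta		Ropsha	RU	/		78	20	58	98	62	3
Baltic Sea Basin	S. trutta (anadromous)		Vistula R.	PL	23		80	14/6	60	100	63	
Baltic Sea Basin	S. trutta (anadromous)		Vistula R.	PL	21		80	22	58	102	64	
Baltic Sea Basin	S. trutta		Vistula R.	PL	18		80	22	58	102	65	
Baltic Sea Basin	S. trutta (lacustrine)		Wdzydze L.	PL	13		80	22	58	102	65	
Baltic Sea Basin	S. trutta		Gawrych Ruda Hatchery	PL	21		80	22	58	102	66	
Black Sea Basin	S. labrax		Local hatchery	GE	embryos		80	18	62	98	67	1
Black Sea Basin	S. labrax		Local hatchery	GE	6		80	22	58	102	68	
Black Sea Basin	S. trutta	*	Black R.	GE	8		80-82	20-22	60	100-104	68	3
Black Sea Basin	S. trutta	*	Bzyb R.	GE	9		82	22	60	104	68	1
Black Sea Basin	S. trutta	*	Gumista R.	GE	9		82	22	60	104	68	1
Black Sea Basin	S. trutta	*	Kodori R.	GE	8		80-82	20-22	60	100-104	68	1; 2
Black Sea Basin	S. trutta	*	Bicaz, Prejmer, Azuga	RO	/		80	24	56	104	69	1; 2
Black Sea Basin	S. trutta	*	Western-Middle Carpathians	RO	/		80	24	56	104	69	1; 2
Caspian Sea Basin	S. caspius				embryos		80	18	62	98	70	1
Caspian Sea Basin	S. caspius		Kura R.	AZ	2		82	20	62	102	68	1; 2
Caspian Sea Basin	S. ischchan "winter ischchan"		Sevan L.	AR	11		80	16	64	96	67; 71	1; 2
Caspian Sea Basin	S. ischchan "gegarkuni"		Sevan L.	AR	17		80	18	62	98	67; 71	1; 2
Caspian Sea Basin	S. ischchan "summer ischchan"		Sevan L.	AR	23		82	18	64	100	67; 71	1; 2
Caspian Sea Basin	S. ischchan "bodjak"		Sevan L.	AR	7		82	16	66	98	67; 71	1; 2
Caspian Sea Basin	S. trutta "alabalach"	*	Argichi R.	AR	8		80	16	64	96	72	1
Caspian Sea Basin	S. trutta		Marmarik R.	AR	/		82	16	66	98	73	1
Caspian Sea Basin	S. trutta		Vedi R.	AR	/		78	20	58	98	73	1
Caspian Sea Basin	S. trutta	*	Azat R.	AR	8		78	20	58	98	68	1
Caspian Sea Basin	S. trutta	*	Arindg R.		7		80	18	62	98	68	1
Caspian Sea Basin	S. trutta	*	Vedi R.	AR	18		78	20	58	98	68	1
Caspian Sea Basin	S. trutta	*	Korotan R.		15		80	20	60	100	68	1
Caspian Sea Basin	S. trutta	*	Dzeoraget R.	AR	8		80	20	60	100	68	1
Caspian Sea Basin	S. trutta	*	Kcia R.		3		82	20	62	102	68	1
Caspian Sea Basin	S. trutta	*	Kyuretchai R.		9		84	16	68	100	68	1
Caspian Sea Basin	S. trutta	*	Marmarik R.	AR	7		82	16	66	98	68	1
Caspian Sea Basin	S. trutta	*	Ochtchi R.		8		82	20	62	102	68	1
Caspian Sea Basin	S. trutta	*	Chatchen R.		7		80	20	60	100	68	1
Caspian Sea Basin	S. trutta	*	Tchaki R.		8		82	18	64	100	68	1
Caspian Sea Basin	S. trutta	*	Goygol L.	AZ	7		80	20	60	100	68	1
Caspian Sea Basin	S. trutta	*	Tabackuri L.	GE	15		80	20	60	100	68	1
Northern Sea Basin, European Atlantic coast	S. trutta		Cares R.	ES	49		80	22-23	57-58	102-103	74	1
Northern Sea Basin, European Atlantic coast	S. trutta		Pyrenees hatchery	ES	44		81	22-24	57-59	103-105	74	1
Northern Sea Basin, European Atlantic coast	S. trutta (anadromous)		Galicia	ES	14		80	20	60	100	75	4
Northern Sea Basin, European Atlantic coast	S. trutta (local hatchery strain)		Galicia	ES	19		80	20	60	100	75	4
Northern Sea Basin, European Atlantic coast	S. trutta		Pšovka Cr.	CZ	10		80	14/4	62	98	76	4
Northern Sea Basin, European Atlantic coast	S. trutta		Navia, Tambre, Umia, Mino R.	ES	133		78-80	20	58-60	98-100	77; 78	2; 4; 5
Northern Sea Basin, European Atlantic coast	S. trutta		Galicia	ES	15		80	20	60	100	79	3
Northern Sea Basin, European Atlantic coast	S. trutta		Hatchery stock AT lineage	IT	20		80	14/8	58	102	55	2; 5
Northern Sea Basin, European Atlantic coast	S. trutta		Loch Lomond	SCT	6		79-80	21-22	58-59	100-102	80	3
Northern Sea Basin, European Atlantic coast	S. trutta		Norway (migratory)	NO	/		80	14	66	94	81	3
Northern Sea Basin, European Atlantic coast	S. trutta		Germany	DE	6		78-82	20-26	52-62	102-104	82	2
Northern Sea Basin, European Atlantic coast	S. trutta		10 localities across all Sweden	SW	14		80	20	60	100	83	1
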