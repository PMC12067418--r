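patient_id	centre	n_seizures	n_channels	modality
pt1	nih	4	84	ECOG
pt2	nih	3	62	ECOG
pt3	nih	2	97	ECOG
pt6	nih	3	80	ECOG
pt8	nih	3	59	ECOG
pt10	nih	3	55	ECOG
pt11	nih	4	78	ECOG
pt13	nih	4	117	ECOG
pt15	nih	4	71	ECOG
pt16	nih	3	46	ECOG
ummc002	ummc	3	49	ECOG
ummc005	ummc	2	48	ECOG
ummc008	ummc	2	50	ECOG
ummc009	ummc	3	45	ECOG
jh05	ummc	5	85	ECOG
HUP065	hup	3	64	ECOG
HUP070	hup	5	63	ECOG
HUP074	hup	5	114	ECOG
HUP082	hup	5	86	ECOG
HUP087	hup	2	84	ECOG
HUP088	hup	3	54	ECOG
HUP089	hup	4	94	ECOG
HUP094	hup	3	83	ECOG
HUP097	hup	5	92	ECOG
HUP105	hup	2	55	ECOG
HUP106	hup	3	115	ECOG
HUP107	hup	5	117	ECOG
HUP111	hup	5	101	ECOG
HUP116	hup	3	50	SEEG
HUP117	hup	3	49	SEEG
HUP123	hup	4	117	ECOG
HUP126	hup	4	125	ECOG
HUP130	hup	5	120	SEEG
HUP139	hup	3	73	SEEG
HUP140	hup	3	86	SEEG
HUP141	hup	5	113	SEEG
HUP142	hup	3	108	SEEG
HUP144	hup	5	111	SEEG
HUP146	hup	3	122	SEEG
HUP148	hup	5	101	SEEG
HUP150	hup	5	89	SEEG
HUP157	hup	5	164	SEEG
HUP160	hup	3	102	SEEG
HUP163	hup	3	156	SEEG
HUP164	hup	3	176	SEEG
HUP177	hup	3	172	SEEG
HUP180	hup	5	111	SEEG
HUP185	hup	5	113	SEEG
pt1	chum	11	97	GSD
pt2	chum	5	104	GSD
pt7	chum	9	61	GSD
pt9	chum	4	105	GSD
pt11	chum	7	91	GSD
pt12	chum	3	88	GSD
pt14	chum	4	73	GSD
pt16	chum	5	101	GSD
pt17	chum	4	114	GSD
pt21	chum	5	111	GSD
pt22	chum	5	108	GSD
pt23	chum	2	99	GSD
pt25	chum	3	113	GSD
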