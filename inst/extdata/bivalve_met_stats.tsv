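species	accession	met_anticodons	p_uua	p_aua	diff
Crassostrea angulata	EU672832	CAU/CAU	63.20	49.74	13.46
Crassostrea ariakensis	EU672835	CAU/CAU	62.93	56.67	6.27
Crassostrea gigas	AF177226	CAU/CAU	65.27	48.98	16.29
Crassostrea hongkongensis	EU672834	CAU/CAU	71.94	64.52	7.42
Crassostrea sikamea	EU672833	CAU/CAU	66.67	46.07	20.59
Crassostrea virginica	AY905542	CAU/CAU	63.01	49.49	13.52
Crassostrea nippona	HM015198	CAU/CAU	70.98	64.32	6.66
Crassostrea iredalei	FJ841967	CAU/CAU	73.26	55.43	17.82
Saccostrea mordax	FJ841968	CAU/CAU	69.04	59.46	9.58
Ostrea denselamellosa	HM015199	CAU/CAU	66.42	49.46	16.96
Sinonovacula constricta	EU880278	CAU	64.69	56.41	8.28
Argopecten irradians	EU023915	CAU	50.39	37.76	12.63
Mimachlamys nobilis	FJ415225	CAU/CAU	57.62	50.61	7.01
Chlamys farreri	EU715252	CAU/CAU	60.90	58.08	2.82
Placopecten magellanicus	DQ088274	4CAU/5UAU	37.60	33.33	4.27
Meretrix petechialis	EU145977	CAU	56.97	54.55	2.42
Meretrix meretrix	NC_013188	CAU	58.65	54.55	4.11
Acanthocardia tuberculata	DQ632743	CAU/CAU	65.90	56.42	9.48
Hiatella arctica	DQ632742	CAU/CAU	73.96	60.73	13.23
Lucinella divaricata	EF043342	CAU	56.60	55.62	0.99
Loripes lacteus	EF043341	CAU	55.71	49.71	5.99
Venerupis philippinarum F	AB065375	CAU/CAU	80.05	75.40	4.65
Venerupis philippinarum M	AB065374	CAU/CAU	75.24	65.73	9.52
Mytilus trossulus M	DQ198225	CAU/UAU	68.24	72.44	-4.20
Mytilus galloprovincialis M	AY363687	CAU/UAU	66.32	73.68	-7.36
Mytilus edulis M	NC_006161	CAU/UAU	69.75	69.47	0.28
Mytilus trossulus F	DQ198231	CAU/UAU	63.12	67.44	-4.32
Mytilus galloprovincialis F	NC_006886	CAU/UAU	63.70	67.62	-3.92
Mytilus edulis F	AY823624	CAU/UAU	63.12	68.27	-5.15
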