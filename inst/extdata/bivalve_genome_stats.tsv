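species	accession	gt_percent	at_skew	gc_skew	gt3_percent	n_caah	n_wvh
Crassostrea angulata	EU672832	57.69	-0.13	0.20	61.29	0	16
Crassostrea ariakensis	EU672835	57.79	-0.13	0.20	60.30	0	15
Crassostrea gigas	AF177226	57.70	-0.13	0.20	61.18	0	16
Crassostrea hongkongensis	EU672834	57.28	-0.11	0.21	59.28	0	14
Crassostrea sikamea	EU672833	57.85	-0.13	0.21	61.77	0	15
Crassostrea virginica	AY905542	57.02	-0.13	0.16	58.55	0	15
Crassostrea nippona	HM015198	56.61	-0.10	0.19	58.99	0	12
Crassostrea iredalei	FJ841967	56.82	-0.10	0.20	59.78	0	14
Saccostrea mordax	FJ841968	58.53	-0.15	0.21	60.22	0	14
Ostrea denselamellosa	HM015199	58.34	-0.15	0.19	60.39	0	16
Sinonovacula constricta	EU880278	63.59	-0.23	0.36	70.48	0	17
Argopecten irradians	EU023915	62.58	-0.25	0.31	66.40	1	17
Mimachlamys nobilis	FJ415225	63.75	-0.25	0.31	69.82	1	18
Chlamys farreri	EU715252	62.34	-0.18	0.34	67.42	1	18
Placopecten magellanicus	DQ088274	66.57	-0.27	0.40	79.54	2	18
Meretrix petechialis	EU145977	65.02	-0.26	0.39	72.73	0	17
Meretrix meretrix	NC_013188	64.89	-0.25	0.39	72.45	0	17
Acanthocardia tuberculata	DQ632743	58.85	-0.18	0.17	58.51	0	16
Hiatella arctica	DQ632742	59.80	-0.15	0.29	61.12	0	14
Lucinella divaricata	EF043342	63.44	-0.24	0.33	64.98	0	17
Loripes lacteus	EF043341	63.29	-0.23	0.32	66.09	0	19
Venerupis philippinarum F	AB065375	60.08	-0.13	0.36	60.31	0	16
Venerupis philippinarum M	AB065374	59.99	-0.15	0.31	62.96	0	16
Mytilus trossulus M	DQ198225	56.47	-0.09	0.20	54.77	0	14
Mytilus galloprovincialis M	AY363687	56.22	-0.08	0.20	56.24	0	14
Mytilus edulis M	NC_006161	58.06	-0.11	0.25	53.25	0	14
Mytilus trossulus F	DQ198231	58.09	-0.11	0.25	57.55	0	15
Mytilus galloprovincialis F	NC_006886	58.02	-0.11	0.24	57.74	0	15
Mytilus edulis F	AY823624	56.07	-0.08	0.19	57.98	0	15
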