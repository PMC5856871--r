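compound_id	name	formula	monoisotopic_mass	source
CPD0001	water	H2O	18.0105647	CUSTOM
CPD0002	glucose	C6H12O6	180.0633881	CUSTOM
CPD0003	alanine	C3H7NO2	89.0476785	CUSTOM
CPD0004	palmitic acid	C16H32O2	256.2402303	CUSTOM
CPD0005	cholesterol	C27H46O	386.3548661	CUSTOM
CPD0006	glycine	C2H5NO2	75.0320284	CUSTOM
CPD0007	serine	C3H7NO3	105.0425931	CUSTOM
CPD0008	leucine	C6H13NO2	131.0946287	CUSTOM
CPD0009	valine	C5H11NO2	117.0789786	CUSTOM
CPD0010	proline	C5H9NO2	115.0633285	CUSTOM
CPD0011	phenylalanine	C9H11NO2	165.0789786	CUSTOM
CPD0012	tyrosine	C9H11NO3	181.0738932	CUSTOM
CPD0013	tryptophan	C11H12N2O2	204.0898776	CUSTOM
CPD0014	methionine	C5H11NO2S	149.0510493	CUSTOM
CPD0015	cysteine	C3H7NO2S	121.0197492	CUSTOM
CPD0016	lysine	C6H14N2O2	146.1055277	CUSTOM
CPD0017	arginine	C6H14N4O2	174.1116757	CUSTOM
CPD0018	histidine	C6H9N3O2	155.0694765	CUSTOM
CPD0019	glutamine	C5H10N2O3	146.0691422	CUSTOM
CPD0020	glutamic acid	C5H9NO4	147.0531578	CUSTOM
CPD0021	aspartic acid	C4H7NO4	133.0375077	CUSTOM
CPD0022	asparagine	C4H8N2O3	132.0534921	CUSTOM
CPD0023	threonine	C4H9NO3	119.0582432	CUSTOM
CPD0024	lactic acid	C3H6O3	90.0316941	CUSTOM
CPD0025	pyruvic acid	C3H4O3	88.0160440	CUSTOM
CPD0026	citric acid	C6H8O7	192.0270026	CUSTOM
CPD0027	succinic acid	C4H6O4	118.0266087	CUSTOM
CPD0028	fumaric acid	C4H4O4	116.0109586	CUSTOM
CPD0029	malic acid	C4H6O5	134.0215233	CUSTOM
CPD0030	2-oxoglutaric acid	C5H6O5	146.0215233	CUSTOM
CPD0031	creatinine	C4H7N3O	113.0589119	CUSTOM
CPD0032	creatine	C4H9N3O2	131.0694765	CUSTOM
CPD0033	urea	CH4N2O	60.0323628	CUSTOM
CPD0034	uric acid	C5H4N4O3	168.0283400	CUSTOM
CPD0035	hypoxanthine	C5H4N4O	136.0385108	CUSTOM
CPD0036	xanthine	C5H4N4O2	152.0334254	CUSTOM
CPD0037	adenine	C5H5N5	135.0544952	CUSTOM
CPD0038	guanine	C5H5N5O	151.0494098	CUSTOM
CPD0039	adenosine	C10H13N5O4	267.0967539	CUSTOM
CPD0040	inosine	C10H12N4O5	268.0807695	CUSTOM
CPD0041	caffeine	C8H10N4O2	194.0803756	CUSTOM
CPD0042	cholic acid	C24H40O5	408.2875744	CUSTOM
CPD0043	stearic acid	C18H36O2	284.2715304	CUSTOM
CPD0044	oleic acid	C18H34O2	282.2558803	CUSTOM
CPD0045	linoleic acid	C18H32O2	280.2402303	CUSTOM
CPD0046	arachidonic acid	C20H32O2	304.2402303	CUSTOM
CPD0047	myristic acid	C14H28O2	228.2089301	CUSTOM
CPD0048	glycerol	C3H8O3	92.0473441	CUSTOM
CPD0049	carnitine	C7H15NO3	161.1051934	CUSTOM
CPD0050	taurine	C2H7NO3S	125.0146638	CUSTOM
CPD0051	glucose 6-phosphate	C6H13O9P	260.0297185	CUSTOM
CPD0052	AMP	C10H14N5O7P	347.0630843	CUSTOM
CPD0053	glutathione	C10H17N3O6S	307.0838060	CUSTOM
CPD0054	sphingosine	C18H37NO2	299.2824294	CUSTOM
CPD0055	LPC 16:0	C24H50NO7P	495.3324895	CUSTOM
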