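condition	gene_id	Z	P	gene_name	reported_role
uncontaminated	78221327	6.336	0.000	cytochrome	module_hub
uncontaminated	104304169	5.091	0.000	pmoA	module_hub
uncontaminated	10863129	4.884	0.000	nifH	module_hub
uncontaminated	46106	4.287	0.000	nifH	module_hub
uncontaminated	146295293	3.451	0.000	CadA	module_hub
uncontaminated	18461102	3.270	0.000	phenol_oxidase	module_hub
uncontaminated	156719686	3.000	0.000	mer	module_hub
uncontaminated	109645564	2.973	0.000	nrfA	module_hub
uncontaminated	104304111	2.958	0.000	pmoA	module_hub
uncontaminated	57903688	2.885	0.000	gyrB	module_hub
uncontaminated	28566177	2.749	0.133	gyrB	module_hub
uncontaminated	103487991	2.682	0.000	mer	module_hub
contaminated	88789151	2.828	0.328	MFS_antibiotic	module_hub
contaminated	30248392	2.711	0.135	czcA	module_hub
contaminated	6324893	1.250	0.747	alkK	connector
contaminated	62468076	1.250	0.743	bco	connector
contaminated	33413585	0.854	0.743	endochitinase	connector
contaminated	88701127	-0.732	0.722	mauAB	connector
contaminated	89512930	-0.732	0.722	nifH	connector
contaminated	118705772	2.043	0.716	mauAB	connector
contaminated	67933455	2.043	0.703	CODH	connector
contaminated	91802739	0.457	0.698	czcA	connector
contaminated	12659186	1.250	0.695	nifH	connector
contaminated	192808970	0.432	0.685	Tet	connector
contaminated	119963032	-0.276	0.684	nmoA	connector
contaminated	82724314	0.138	0.666	endochitinase	connector
contaminated	133919284	-0.555	0.663	B_lactamase_A	connector
contaminated	89075780	-0.719	0.660	B_lactamase_A	connector
contaminated	56476743	-0.276	0.658	ebdABC	connector
contaminated	2196830	0.588	0.653	gyrB	connector
contaminated	157363044	0.668	0.644	pcc	connector
contaminated	118685870	-0.515	0.642	proO	connector
contaminated	110647328	0.905	0.640	czcA	connector
contaminated	67920251	-0.065	0.628	pcaG	connector
contaminated	87135386	0.552	0.626	mauAB	connector
contaminated	94554094	-0.065	0.626	CopA	connector
contaminated	15806552	0.915	0.617	pcc	connector
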