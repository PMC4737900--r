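condition	n_original	s_t	n	L	scale_free_r	avgK	GD	avgCC	M	n_modules	rand_GD_mean	rand_GD_sd	rand_avgCC_mean	rand_avgCC_sd	rand_M_mean	rand_M_sd
uncontaminated	3367	0.95	754	1150	-0.86	3.05	0.907	0.153	0.79	141	3.016	0.044	0.162	0.005	0.455	0.012
contaminated	771	0.96	256	957	-0.88	7.48	1.968	0.292	0.46	33	2.826	0.101	0.081	0.008	0.233	0.007
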