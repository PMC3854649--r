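gene_id	symbol	p_value	fold_change
2523	Fut1	0.154618	1.079052
2524	FUT2	0.085096	1.506772
2717	Gla	0.048796	7.793774
3073	HexA	0.271048	5.073008
3074	Hexb	0.166863	7.790576
4668	nagA	0.063709	2.171953
6482	ST3GAL1	0.275852	2.535963
6483	ST3GAL2	0.13051	2.067693
6489	ST8SIA1	0.357908	7.755918
8706	B3galnt1	0.029243	0.863497
10317	B3galt5	0.475799	3.853211
10690	fut9	0.275609	1.418501
26301	Gbgt1	0.338454	0.097302
53947	A4GALT	0.621914	0.619847
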