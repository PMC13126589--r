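patient_id	arm	hr_status	pfs_months	pfs_event	os_months	os_event	adjuvant_cht	adjuvant_taxanes	adjuvant_ht	dfi_ge_12m	sites_ge_3	visceral	age_ge_65	node_positive	grading	toxicity	ecog	rs833061	rs1870377	rs11133360	rs4073
S0001	PTX_BEV	positive	6.96655	1	8.35477	1	1	0	0	1	0	1	1	0	3	g1_2	0_1	CT	TT	TT	AT
S0002	PTX_BEV	positive	28.7961	1	48.6392	1	1	0	1	1	0	0	0	1	2	g1_2	0_1	CT	AT	CT	TT
S0003	PTX_BEV	positive	14.9056	1	30.5581	1	1	0	1	1	0	1	0	0	2	g1_2	0_1	TT	AT	TT	AT
S0004	PTX_BEV	positive	2.58481	1	22.3464	1	0	0	1	1	0	1	0	1	2	g1_2	0_1	CT	TT	CT	AA
S0005	PTX_BEV	positive	60	0	60	0	1	1	1	0	0	1	0	1	2	g1_2	0_1	TT	TT	CT	TT
S0006	PTX_BEV	positive	60	0	60	0	1	0	0	0	1	1	0	0	2	g3_4	0_1	CT	AA	CT	AA
S0007	PTX_BEV	positive	6.21948	1	19.4877	1	1	0	1	1	0	1	1	1	2	g3_4	0_1	CT	TT	TT	AA
S0008	PTX_BEV	positive	4.4246	1	5.74841	1	1	1	0	1	0	1	1	0	2	g3_4	0_1	TT	TT	CT	AA
S0009	PTX_BEV	positive	15.1819	1	59.36	1	0	0	1	0	0	0	1	1	2	g1_2	0_1	CT	AT	CC	AA
S0010	PTX_BEV	positive	20.6524	1	25.479	1	1	0	1	0	0	1	0	1	2	g1_2	0_1	CC	AT	TT	AT
S0011	PTX_BEV	positive	25.4831	1	32.4222	1	0	0	1	1	0	1	1	0	2	g1_2	2	CT	TT	CT	AT
S0012	PTX_BEV	positive	10.3963	1	60	0	1	0	0	1	0	0	0	1	3	g3_4	0_1	TT	TT	CC	AA
S0013	PTX_BEV	positive	3.79934	1	6.83134	1	1	0	1	0	0	1	0	1	2	g1_2	0_1	CT	TT	CC	AT
S0014	PTX_BEV	positive	16.9396	1	18.437	1	1	0	0	1	0	1	0	1	2	g1_2	0_1	CT	TT	TT	AA
S0015	PTX_BEV	positive	60	0	60	0	1	1	1	0	0	1	1	1	2	g1_2	0_1	CC	TT	CT	AT
S0016	PTX_BEV	positive	11.6739	1	17.3291	1	0	1	0	1	0	0	1	1	2	g1_2	0_1	CT	TT	CC	AT
S0017	PTX_BEV	positive	13.5933	1	20.7772	1	1	0	1	0	0	1	1	1	3	g1_2	0_1	CC	AT	CT	AT
S0018	PTX_BEV	positive	46.0824	1	48.5755	1	0	1	1	0	0	1	0	0	2	g1_2	0_1	CC	AT	CT	AA
S0019	PTX_BEV	positive	17.1378	1	52.9579	1	1	0	1	1	0	0	0	0	2	g3_4	0_1	CT	TT	TT	TT
S0020	PTX_BEV	positive	21.8851	1	44.7814	1	1	1	1	1	0	1	0	1	2	g3_4	0_1	TT	TT	CC	AT
S0021	PTX_BEV	positive	11.9987	1	18.8309	1	0	0	1	0	1	1	0	1	2	g1_2	0_1	TT	AT	CT	AT
S0022	PTX_BEV	positive	3.82587	1	9.47777	1	0	1	1	0	0	0	0	0	2	g1_2	0_1	CC	AA	CT	AA
S0023	PTX_BEV	positive	12.2438	1	44.9602	1	1	0	1	0	0	0	1	0	2	g1_2	0_1	CC	AT	TT	TT
S0024	PTX_BEV	positive	19.9436	1	46.2024	1	1	0	1	0	0	1	1	1	2	g1_2	0_1	CC	TT	TT	AT
S0025	PTX_BEV	positive	3.89964	1	60	0	0	0	0	1	0	1	1	1	2	g1_2	0_1	CT	AT	CT	AA
S0026	PTX_BEV	positive	3.17214	1	22.1725	1	0	0	0	1	1	1	0	0	3	g1_2	0_1	CC	AT	TT	AT
S0027	PTX_BEV	positive	25.1253	1	60	0	0	1	1	1	1	1	0	1	2	g1_2	0_1	CT	AT	CC	TT
S0028	PTX_BEV	positive	10.6767	1	30.852	1	1	0	1	1	0	1	1	1	3	g1_2	0_1	TT	AT	CT	TT
S0029	PTX	positive	10.045	1	27.0394	1	0	1	1	0	0	1	0	0	2	g3_4	0_1	TT	AT	CC	AT
S0030	PTX	positive	13.8063	1	15.1089	1	0	0	0	1	0	1	0	1	2	g1_2	0_1	CT	TT	CT	AT
S0031	PTX	positive	1.5968	1	8.99915	1	0	0	0	1	0	1	1	1	2	g1_2	0_1	TT	TT	CT	AT
S0032	PTX	positive	6.70401	1	20.0015	1	1	0	1	0	0	0	0	1	2	g1_2	2	CT	AT	CT	AA
S0033	PTX	positive	23.5746	1	31.2986	1	0	1	0	1	1	1	0	0	2	g1_2	0_1	CC	AT	CT	TT
S0034	PTX	positive	15.369	1	32.0808	1	1	0	1	0	0	1	0	1	2	g1_2	0_1	CT	TT	CT	AT
S0035	PTX	positive	2.75072	1	16.8179	1	0	1	1	0	1	0	1	0	3	g1_2	0_1	CT	AT	CT	TT
S0036	PTX	positive	4.35175	1	6.71254	1	1	0	1	1	0	0	0	1	2	g1_2	0_1	CT	AT	CC	TT
S0037	PTX	positive	15.3967	1	23.0096	1	0	0	0	1	0	1	0	1	2	g1_2	0_1	TT	AT	TT	AT
S0038	PTX	positive	3.26688	1	5.84842	1	0	0	1	1	0	1	0	1	2	g1_2	2	TT	TT	CT	AA
S0039	PTX	positive	6.33981	1	60	0	0	0	1	1	0	1	0	0	2	g3_4	0_1	CC	AT	CC	TT
S0040	PTX	positive	3.30224	1	7.97623	1	1	0	1	1	0	1	0	1	3	g1_2	0_1	CC	TT	CC	AT
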