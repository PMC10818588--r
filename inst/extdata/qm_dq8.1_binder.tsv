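# allele: HLA-DQ8.1
# label: binder
# n_peptides: 463
AA	p1	p2	p3	p4	p5	p6	p7	p8	p9
Ala	0.068	0.373	0.494	0.699	0.262	0.531	0.378	0.152	0.031
Arg	-0.111	0.004	-0.085	-0.122	-0.027	-0.122	-0.111	0.047	-0.096
Asn	-0.122	-0.053	-0.106	-0.096	-0.074	-0.117	-0.038	-0.080	-0.106
Asp	0.036	-0.038	0.020	-0.011	-0.022	-0.038	0.083	-0.038	0.489
Cys	-0.122	-0.122	-0.122	-0.090	-0.122	-0.122	-0.122	-0.122	-0.122
Gln	-0.106	0.004	-0.090	-0.106	-0.022	-0.111	0.052	-0.074	0.010
Glu	0.157	0.215	-0.022	-0.053	0.194	0.062	0.494	0.383	0.878
Gly	-0.106	-0.053	0.257	-0.074	-0.032	-0.111	-0.090	0.041	0.004
His	-0.101	-0.006	-0.096	-0.122	-0.069	-0.117	-0.074	-0.069	-0.117
Ile	0.199	-0.006	-0.080	0.189	-0.017	0.052	-0.043	-0.069	-0.090
Leu	0.089	-0.074	-0.069	0.004	-0.027	-0.064	-0.006	0.073	-0.080
Lys	-0.111	0.004	-0.106	-0.122	0.052	-0.122	-0.090	0.010	-0.117
Met	-0.106	-0.101	-0.101	-0.101	-0.090	-0.111	-0.117	-0.111	-0.096
Phe	0.099	-0.074	-0.048	-0.069	-0.074	-0.122	-0.111	-0.074	-0.111
Pro	0.099	-0.117	-0.038	-0.122	-0.032	0.115	0.020	0.162	-0.122
Ser	-0.048	0.015	0.226	0.057	0.062	0.089	-0.006	0.004	-0.011
Thr	-0.074	0.068	0.147	0.010	0.052	0.078	-0.053	-0.059	-0.080
Trp	-0.038	-0.106	-0.111	-0.101	-0.106	-0.122	-0.106	-0.117	-0.106
Tyr	0.089	-0.011	-0.074	-0.122	-0.085	-0.111	-0.064	-0.069	-0.101
Val	0.210	0.078	0.004	0.352	0.178	0.462	0.004	0.010	-0.059
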