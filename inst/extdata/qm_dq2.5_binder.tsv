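# allele: HLA-DQ2.5
# label: binder
# n_peptides: 125
AA	p1	p2	p3	p4	p5	p6	p7	p8	p9
Ala	-0.109	0.245	0.286	0.036	0.161	0.286	0.099	0.057	-0.005
Arg	-0.130	-0.047	-0.109	-0.130	-0.047	-0.130	-0.130	-0.068	-0.109
Asn	-0.089	-0.005	-0.068	-0.068	-0.047	-0.047	-0.130	-0.109	-0.089
Asp	0.016	0.099	0.016	0.286	0.057	0.224	0.411	0.036	0.016
Cys	-0.130	-0.130	-0.109	-0.130	-0.130	-0.130	-0.130	-0.130	-0.130
Gln	-0.005	-0.026	-0.005	-0.047	0.016	-0.047	-0.089	0.036	-0.068
Glu	0.078	0.224	0.224	0.536	0.182	0.474	0.870	0.224	0.495
Gly	-0.089	0.036	0.203	0.036	0.286	-0.068	-0.068	-0.068	-0.047
His	-0.130	-0.109	-0.130	-0.109	-0.130	-0.130	-0.130	-0.047	-0.109
Ile	0.161	-0.026	0.057	0.099	0.036	-0.089	-0.089	-0.005	0.016
Leu	0.182	-0.089	-0.005	0.057	-0.005	0.057	0.016	0.141	0.182
Lys	-0.130	-0.005	-0.130	-0.130	0.016	-0.130	-0.130	-0.047	-0.130
Met	-0.089	-0.089	-0.109	-0.130	-0.130	-0.109	-0.130	-0.089	0.057
Phe	0.078	-0.109	-0.005	-0.089	-0.089	-0.109	-0.130	-0.068	0.141
Pro	0.224	-0.089	-0.005	-0.109	-0.109	0.099	-0.089	0.141	-0.068
Ser	-0.130	0.120	0.078	0.016	0.099	0.016	-0.026	-0.005	-0.026
Thr	-0.047	0.099	-0.047	-0.047	-0.005	-0.068	0.057	0.016	-0.047
Trp	-0.068	-0.109	-0.130	-0.130	-0.089	-0.130	-0.109	-0.089	-0.068
Tyr	0.016	-0.068	-0.005	-0.109	-0.068	-0.068	-0.089	-0.026	-0.047
Val	0.391	0.078	-0.005	0.161	-0.005	0.099	0.016	0.099	0.036
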