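# allele: HLA-DQ8.1
# label: non-binder
# n_peptides: 463
AA	p1	p2	p3	p4	p5	p6	p7	p8	p9
Ala	-0.140	-0.140	-0.140	-0.140	-0.140	-0.140	-0.140	-0.140	-0.140
Arg	0.108	-0.140	0.217	0.108	-0.140	0.102	0.229	-0.140	0.108
Asn	0.181	-0.140	0.235	0.102	0.672	0.132	-0.140	0.793	0.138
Asp	-0.140	-0.140	-0.140	-0.140	-0.140	-0.140	-0.140	-0.140	-0.140
Cys	0.090	0.490	0.211	-0.140	0.860	0.187	0.260	0.751	0.126
Gln	0.138	-0.140	0.211	0.151	-0.140	0.145	-0.140	-0.140	-0.140
Glu	-0.140	-0.140	-0.140	0.145	-0.140	-0.140	-0.140	-0.140	-0.140
Gly	0.169	-0.140	-0.140	0.084	-0.140	0.169	0.302	-0.140	-0.140
His	0.126	-0.140	0.272	0.096	-0.140	0.193	-0.140	-0.140	-0.140
Ile	-0.140	-0.140	0.157	-0.140	-0.140	-0.140	-0.140	-0.140	0.066
Leu	0.102	0.611	0.199	0.108	0.854	0.132	0.211	0.842	0.084
Lys	0.175	-0.140	0.181	0.145	-0.140	0.126	0.235	-0.140	0.078
Met	-0.140	-0.140	-0.140	-0.140	-0.140	-0.140	0.302	-0.140	-0.140
Phe	-0.140	0.557	-0.140	0.060	-0.140	0.084	-0.140	-0.140	0.072
Pro	-0.140	0.587	-0.140	0.120	-0.140	-0.140	-0.140	-0.140	0.145
Ser	0.175	-0.140	-0.140	-0.140	-0.140	-0.140	-0.140	-0.140	0.138
Thr	0.138	-0.140	-0.140	-0.140	-0.140	-0.140	0.284	-0.140	0.138
Trp	-0.140	-0.140	-0.140	-0.140	-0.140	-0.140	-0.140	-0.140	-0.140
Tyr	-0.140	-0.140	-0.140	0.145	-0.140	0.132	-0.140	-0.140	-0.140
Val	-0.140	-0.140	-0.140	-0.140	-0.140	-0.140	-0.140	-0.140	0.169
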