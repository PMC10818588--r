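# allele: HLA-DQ2.5
# label: non-binder
# n_peptides: 125
AA	p1	p2	p3	p4	p5	p6	p7	p8	p9
Ala	-0.019	0.799	-0.095	0.042	-0.095	-0.095	0.057	0.239	0.133
Arg	0.057	-0.095	0.148	0.148	0.572	0.133	0.178	-0.095	0.133
Asn	0.133	-0.095	-0.095	-0.095	-0.095	0.208	-0.034	-0.095	-0.095
Asp	0.178	-0.095	0.208	-0.095	-0.095	-0.095	-0.095	-0.095	-0.095
Cys	-0.095	-0.095	-0.095	-0.095	-0.095	-0.095	-0.095	-0.095	-0.095
Gln	-0.095	-0.095	-0.095	0.027	-0.095	0.117	0.027	0.193	0.148
Glu	0.133	-0.095	0.208	-0.095	-0.095	-0.095	-0.095	-0.095	-0.095
Gly	0.284	-0.095	-0.095	0.087	-0.095	0.208	0.102	-0.095	-0.095
His	-0.095	-0.095	-0.095	-0.095	-0.095	-0.095	-0.095	-0.095	-0.095
Ile	-0.095	-0.095	0.269	0.042	-0.095	-0.095	-0.095	0.375	-0.095
Leu	-0.095	0.905	0.193	0.057	0.345	0.027	0.057	0.254	-0.095
Lys	0.011	-0.095	0.299	-0.019	0.375	0.042	0.087	-0.095	0.027
Met	-0.095	-0.095	-0.095	0.042	-0.095	-0.095	-0.095	-0.095	0.223
Phe	-0.095	-0.095	-0.095	-0.004	-0.095	-0.095	-0.095	-0.095	-0.095
Pro	-0.095	-0.095	-0.095	-0.095	-0.095	0.042	0.027	-0.095	0.057
Ser	0.087	-0.095	-0.095	0.011	-0.095	0.072	0.102	-0.095	0.299
Thr	0.178	-0.095	-0.095	0.148	0.223	0.042	0.117	0.360	0.117
Trp	-0.095	-0.095	-0.095	0.133	-0.095	-0.095	-0.095	-0.095	-0.095
Tyr	-0.095	-0.095	-0.095	-0.095	-0.095	-0.095	-0.095	-0.095	-0.095
Val	-0.095	-0.095	-0.095	-0.049	-0.095	0.057	0.133	-0.095	-0.095
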