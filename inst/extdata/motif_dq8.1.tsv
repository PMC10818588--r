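# allele: HLA-DQ8.1
p1	R,N,C,Q,G,H,L,K,S,T
p2	C,L,F,P
p3	N,R,C,Q,E,H,I,L,K
p4	R,N,E,Q,G,H,L,K,F,P,Y
p5	N,C,L
p6	N,R,C,Q,G,H,L,K,F,Y
p7	R,C,G,L,K,M,T
p8	N,C,L
p9	R,N,C,I,L,K,F,P,S,T,V
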