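# allele: HLA-DQ2.5
p1	A,R,N,D,E,G,K,S,T
p2	A,L
p3	R,D,E,I,L,K
p4	A,R,Q,G,I,L,K,M,F,S,T,W,V
p5	R,L,K,T
p6	R,N,Q,G,L,K,P,S,T,V
p7	A,N,Q,G,L,K,P,S,T,V
p8	A,Q,I,L,T
p9	A,R,Q,K,M,P,S,T
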