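# Published per-atom Sstate3D values for compound 6k of the antimalarial
# reference dataset (4-aminobicyclo[2.2.2]octan-2-yl 4-aminobutanoates).
atom,element,sstate3d
1,C,0.27653
2,C,4.24474
3,C,-2.11427
4,C,4.25231
5,C,0.49396
6,C,0.52371
7,C,0.28273
8,C,4.2063
9,C,-0.37931
10,C,3.51969
11,C,2.98731
12,C,2.89649
13,C,2.99502
14,C,3.5348
15,O,-0.08644
16,C,-0.10545
17,O,5.5644
18,C,3.75612
19,N,-1.4592
20,C,3.38006
21,C,3.11542
22,C,-0.12941
23,C,3.09432
24,C,3.32881
25,O,4.22234
26,N,-1.30847
27,C,3.52697
28,C,2.9831
29,C,3.01061
30,C,3.54754
31,C,-0.38433
32,C,3.54001
33,C,2.99825
34,C,2.90069
35,C,2.99544
36,C,3.53921
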