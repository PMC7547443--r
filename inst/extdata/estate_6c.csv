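# Published per-atom Sstate3D values for compound 6c of the antimalarial
# reference dataset (4-aminobicyclo[2.2.2]octan-2-yl 4-aminobutanoates).
atom,element,sstate3d
1,C,0.35527
2,C,4.17197
3,C,-2.19195
4,C,4.25527
5,C,0.37013
6,C,0.50352
7,C,0.21375
8,C,4.23211
9,C,-0.24053
10,C,3.50889
11,C,3.00512
12,C,2.94959
13,C,3.09722
14,C,3.69435
15,O,-0.48635
16,C,-0.31876
17,O,5.6053
18,C,3.73854
19,N,-1.66555
20,C,3.314
21,C,2.96595
22,N,-2.22668
23,C,2.94306
24,C,3.25612
25,C,8.9881
26,N,-1.46525
27,C,3.52712
28,C,2.94719
29,C,2.85191
30,C,2.95634
31,C,3.54763
32,C,-0.13708
33,C,3.3945
34,C,2.9161
35,C,2.85145
36,C,2.96557
37,C,3.52272
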