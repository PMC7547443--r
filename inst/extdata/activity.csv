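# Activity table for the reference dataset: IC50 in micromolar against the
# multiresistant K-1 strain of P. falciparum; active flag marks the 17
# compounds classified as active.
id,ic50,active
8c,0.05,1
7c,0.06,1
8f,0.09,1
8l,0.09,1
6c,0.106,1
8b,0.12,1
7l,0.17,1
6i,0.18,1
8i,0.18,1
8d,0.19,1
8e,0.19,1
8h,0.2,1
8a,0.24,1
7f,0.25,1
7b,0.26,1
7i,0.26,1
7h,0.28,1
6a,0.35,0
8g,0.35,0
6h,0.37,0
7e,0.37,0
7g,0.4,0
7a,0.46,0
6f,0.47,0
8k,0.51,0
6g,0.52,0
6b,0.54,0
7d,0.55,0
6e,0.7,0
6d,0.71,0
6k,0.86,0
8j,1.43,0
7k,1.91,0
6j,2.16,0
7j,2.25,0
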