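# Published Pearson correlations between each similarity method and the
# TcIC50 potency similarity, one row per active reference compound.
id,ic50,obabel_fp2,shafts,isida,smsd,mcphd
8c,0.05,0.54,0.66,0.49,0.54,0.84
7c,0.06,0.29,0.62,0.37,0.06,0.8
8f,0.09,0.24,0.6,0.33,0.5,0.48
8l,0.09,0.26,0.62,0.04,0.44,0.55
6c,0.106,-0.11,0.1,-0.03,-0.13,0.64
8b,0.12,0.5,-0.06,0.49,0.45,0.44
7l,0.17,0.03,0.08,-0.07,-0.03,0.36
6i,0.18,-0.37,0.11,-0.2,-0.16,0.25
8i,0.18,0.26,0.64,0.33,0.46,0.56
8d,0.19,0.22,-0.13,0.33,0.27,-0.15
8e,0.19,0.23,0.29,0.33,0.38,0.13
8h,0.2,0.24,0.25,0.33,0.35,0.12
8a,0.24,0.5,-0.11,0.49,0.33,-0.07
7f,0.25,-0.05,0.15,0.2,0.02,0.37
7b,0.26,0.24,-0.09,0.37,-0.04,0.35
7i,0.26,-0.03,0.6,0.2,-0.01,0.4
7h,0.28,-0.05,0.57,0.2,-0.13,-0.02
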