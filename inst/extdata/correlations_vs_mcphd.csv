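# Published Pearson correlations between each comparator method and MCPhd
# similarity vectors, one row per active reference compound.
id,ic50,obabel_fp2,shafts,isida,smsd
8c,0.05,0.57,0.68,0.55,0.43
7c,0.06,0.5,0.69,0.47,0.43
8f,0.09,0.44,0.62,0.24,0.4
8l,0.09,0.45,0.71,0.33,0.53
6c,0.106,0.45,0.5,0.4,0.44
8b,0.12,0.49,0.05,0.36,0.35
7l,0.17,0.44,0.42,0.38,0.47
6i,0.18,0.39,0.46,0.37,0.45
8i,0.18,0.48,0.82,0.5,0.48
8d,0.19,0.26,0.0,0.2,0.3
8e,0.19,0.31,0.42,0.14,0.28
8h,0.2,0.38,0.41,0.3,0.4
8a,0.24,0.42,0.19,0.26,0.4
7f,0.25,0.34,0.33,0.15,0.41
7b,0.26,0.5,-0.02,0.42,0.37
7i,0.26,0.28,0.76,0.22,0.46
7h,0.28,0.26,0.49,0.14,0.34
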