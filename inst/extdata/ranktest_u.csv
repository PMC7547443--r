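# Published Mann-Whitney U statistics (min convention) and two-sided
# asymptotic p-values comparing MCPhd similarity vectors against each
# comparator method, for reference compounds 8c and 7j.
reference,method,u,p
8c,obabel_fp2,131.5,0.0
8c,shafts,117.0,0.0
8c,isida,70.5,0.0
8c,smsd,245.5,0.0
7j,obabel_fp2,33.0,0.0
7j,shafts,34.5,0.0
7j,isida,33.5,0.0
7j,smsd,98.0,0.0
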