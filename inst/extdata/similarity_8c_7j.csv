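# Published molecular-similarity values of every dataset compound against the
# most active (8c) and least active (7j) reference compounds, by method,
# together with the TcIC50 potency-similarity column. IC50 in micromolar.
reference,id,ic50,obabel_fp2,shafts,isida,smsd,mcphd,tcic50
8c,8c,0.05,1.0,1.0,1.0,1.0,1.0,1.0
8c,7c,0.06,0.9,1.0,0.97,0.67,0.97,0.97
8c,8f,0.09,0.91,1.0,0.97,0.95,0.77,0.74
8c,8l,0.09,0.92,1.0,0.9,0.9,0.7,0.74
8c,6c,0.106,0.77,0.87,0.9,0.65,0.77,0.68
8c,8b,0.12,0.98,0.79,1.0,0.97,0.75,0.55
8c,7l,0.17,0.82,0.84,0.88,0.67,0.71,0.37
8c,6i,0.18,0.72,0.87,0.87,0.67,0.53,0.35
8c,8i,0.18,0.92,1.0,0.97,0.93,0.75,0.35
8c,8d,0.19,0.89,0.76,0.97,0.87,0.46,0.33
8c,8e,0.19,0.9,0.93,0.97,0.92,0.56,0.33
8c,8h,0.2,0.91,0.9,0.97,0.9,0.55,0.31
8c,8a,0.24,0.97,0.77,1.0,0.92,0.5,0.25
8c,7f,0.25,0.82,0.89,0.95,0.7,0.74,0.24
8c,7b,0.26,0.88,0.82,0.97,0.65,0.69,0.23
8c,7i,0.26,0.82,1.0,0.95,0.69,0.73,0.23
8c,7h,0.28,0.82,1.0,0.95,0.67,0.53,0.21
8c,6a,0.35,0.73,0.71,0.9,0.59,0.46,0.16
8c,8g,0.35,0.91,0.74,0.97,0.85,0.45,0.16
8c,6h,0.37,0.71,0.82,0.87,0.61,0.37,0.15
8c,7e,0.37,0.8,0.73,0.95,0.68,0.54,0.15
8c,7g,0.4,0.82,0.74,0.95,0.62,0.43,0.14
8c,7a,0.46,0.87,0.71,0.97,0.61,0.61,0.12
8c,6f,0.47,0.71,0.9,0.87,0.68,0.54,0.12
8c,8k,0.51,0.91,0.91,0.9,0.88,0.54,0.11
8c,6g,0.52,0.7,0.71,0.87,0.6,0.38,0.11
8c,6b,0.54,0.76,0.76,0.9,0.63,0.56,0.1
8c,7d,0.55,0.8,0.75,0.95,0.64,0.44,0.1
8c,6e,0.7,0.7,0.86,0.87,0.62,0.38,0.08
8c,6d,0.71,0.68,0.74,0.87,0.61,0.39,0.08
8c,6k,0.86,0.71,0.7,0.81,0.63,0.36,0.06
8c,8j,1.43,0.92,0.75,0.9,0.83,0.42,0.04
8c,7k,1.91,0.82,0.7,0.88,0.65,0.52,0.03
8c,6j,2.16,0.71,0.7,0.81,0.59,0.38,0.02
8c,7j,2.25,0.82,0.78,0.88,0.61,0.42,0.02
7j,8c,0.05,0.82,0.78,0.88,0.61,0.42,0.02
7j,7c,0.06,0.92,0.82,0.9,0.83,0.43,0.03
7j,8f,0.09,0.88,0.8,0.9,0.64,0.6,0.04
7j,8l,0.09,0.89,0.77,0.97,0.61,0.35,0.04
7j,6c,0.106,0.74,0.73,0.81,0.6,0.29,0.05
7j,8b,0.12,0.8,0.88,0.88,0.62,0.33,0.06
7j,7l,0.17,1.0,0.83,1.0,0.92,0.62,0.08
7j,6i,0.18,0.79,0.73,0.83,0.61,0.29,0.09
7j,8i,0.18,0.89,0.78,0.9,0.62,0.43,0.09
7j,8d,0.19,0.86,0.91,0.9,0.68,0.64,0.09
7j,8e,0.19,0.87,0.77,0.9,0.65,0.42,0.09
7j,8h,0.2,0.88,0.74,0.9,0.64,0.33,0.09
7j,8a,0.24,0.79,0.87,0.88,0.65,0.69,0.12
7j,7f,0.25,0.99,0.77,0.92,0.87,0.51,0.12
7j,7b,0.26,0.9,0.76,0.9,0.85,0.33,0.13
7j,7i,0.26,1.0,0.82,0.92,0.89,0.44,0.13
7j,7h,0.28,0.99,0.83,0.92,0.92,0.34,0.14
7j,6a,0.35,0.69,0.87,0.81,0.64,0.64,0.18
7j,8g,0.35,0.88,0.88,0.9,0.67,0.71,0.18
7j,6h,0.37,0.78,0.75,0.83,0.63,0.43,0.19
7j,7e,0.37,0.97,0.94,0.92,0.89,0.35,0.19
7j,7g,0.4,1.0,0.84,0.92,0.97,0.73,0.21
7j,7a,0.46,0.88,0.91,0.9,0.89,0.71,0.24
7j,6f,0.47,0.78,0.75,0.83,0.63,0.46,0.25
7j,8k,0.51,0.88,0.72,0.97,0.62,0.35,0.27
7j,6g,0.52,0.77,0.88,0.83,0.66,0.66,0.28
7j,6b,0.54,0.73,0.83,0.81,0.61,0.31,0.29
7j,7d,0.55,0.97,0.87,0.92,0.94,0.74,0.3
7j,6e,0.7,0.77,0.77,0.83,0.64,0.33,0.4
7j,6d,0.71,0.75,0.91,0.83,0.68,0.68,0.4
7j,6k,0.86,0.78,0.85,0.9,0.61,0.37,0.5
7j,8j,1.43,0.89,0.85,0.97,0.65,0.65,0.83
7j,7k,1.91,0.99,0.99,1.0,0.95,0.5,0.97
7j,6j,2.16,0.78,0.86,0.9,0.64,0.64,1.0
7j,7j,2.25,1.0,1.0,1.0,1.0,1.0,1.0
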