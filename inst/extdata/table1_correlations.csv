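participant_id,r_D_IS,r_D_A,r_A_IS
29,-0.60,0.24,0.31
50,-0.54,0.24,0.41
37,-0.53,-0.11,0.75
41,-0.50,0.31,0.52
27,-0.46,0.67,0.17
14,-0.45,0.29,0.48
16,-0.36,0.38,0.60
10,-0.36,0.46,0.54
20,-0.36,0.04,0.64
19,-0.34,-0.02,0.81
44,-0.34,0.22,0.71
26,-0.12,0.46,0.64
38,-0.09,0.24,0.80
17,-0.08,0.34,0.74
33,-0.03,0.66,0.58
21,-0.02,0.52,0.48
32,0.04,0.47,0.67
42,0.05,0.47,0.77
46,0.07,0.31,0.85
30,0.08,0.53,0.74
13,0.10,0.51,0.80
45,0.11,0.59,0.70
11,0.19,0.66,0.68
31,0.27,0.75,0.71
39,0.27,0.74,0.72
43,0.27,0.80,0.66
40,0.28,0.88,0.57
25,0.29,0.64,0.71
18,0.32,0.81,0.66
36,0.38,0.75,0.76
12,0.39,0.65,0.88
35,0.40,0.75,0.79
24,0.44,0.57,0.81
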