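subject,approx_fusion_eer,detail_fusion_eer
1,0.00,0.00
2,19.04,17.46
3,12.07,9.70
4,19.83,20.04
5,18.89,13.00
6,4.60,4.17
7,13.36,14.08
8,24.21,19.11
9,14.80,14.08
10,18.10,17.03
11,10.06,4.45
12,15.52,22.49
13,12.72,13.99
14,22.56,24.71
15,20.55,17.10
16,22.84,20.76
17,13.22,15.73
18,14.66,10.13
19,7.11,4.74
20,16.38,9.55
21,13.58,11.35
22,10.20,12.72
23,2.08,2.08
24,19.97,9.27
25,10.13,9.48
26,0.00,0.00
27,8.91,8.76
28,27.23,28.81
29,15.54,14.83
30,3.46,3.05
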