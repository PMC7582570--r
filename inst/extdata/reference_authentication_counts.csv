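threshold_pct,patients_accepted,patients_rejected,nonpatients_accepted,nonpatients_rejected
9,54,46,0,2000
10,56,44,0,2000
11,81,19,6,1994
12,84,16,8,1992
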