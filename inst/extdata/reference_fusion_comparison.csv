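configuration,bior1.1,bior1.3
approx_subband3_eer,16.66,16.56
detail_subband3_eer,16.41,16.56
approx_fusion_eer,14.00,14.83
detail_fusion_eer,13.80,14.89
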