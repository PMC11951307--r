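vessel,pr_mean,pr_sd,non_mean,non_sd
LM,0.57,0.84,0.13,0.43
LAD,2.02,0.75,0.55,0.87
LCX,1.17,1.03,0.26,0.63
RCA,1.46,1.10,0.35,0.71
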