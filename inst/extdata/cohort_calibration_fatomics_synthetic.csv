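feature,pr_mean,pr_sd,non_mean,non_sd,clamp01
SR4_Pro_90_70,0.16,0.06,0.10,0.05,1
SR5_Pro_90_70,0.14,0.06,0.09,0.05,1
SR3_Pro_170_150,0.06,0.03,0.09,0.04,1
SR3_Pro_150_130,0.10,0.04,0.13,0.05,1
SR4_Pro_110_90,0.22,0.06,0.19,0.06,1
SR2_Pro_90_70,0.12,0.05,0.09,0.05,1
eat_volume_mm3,130000,40000,110000,38000,0
eat_mean_hu,-82,8,-87,8,0
eat_thickness_mean_mm,6.1,1.6,5.4,1.5,0
eat_skewness,0.35,0.40,0.20,0.40,0
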