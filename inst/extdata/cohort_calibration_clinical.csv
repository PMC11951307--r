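feature,type,pr_param1,pr_param2,non_param1,non_param2,clamp_min
male,binary,0.737,NA,0.470,NA,NA
bmi,continuous,28.6,4.7,30.1,5.9,10
age,continuous,60.5,8.0,55.7,9.6,18
diabetes,binary,0.124,NA,0.106,NA,NA
height_m,continuous,1.72,0.09,1.69,0.10,1.2
weight_kg,continuous,84.1,15.1,86.0,18.9,30
cigarettes_per_day,continuous,2.9,6.6,2.8,7.3,0
hypertension,binary,0.403,NA,0.325,NA,NA
total_cholesterol,continuous,5.04,1.94,5.02,1.82,0
hdl_cholesterol,continuous,0.92,0.66,1.06,0.70,0
chd_family_history,binary,0.447,NA,0.443,NA,NA
sbp,continuous,140.4,21.5,137.3,25.0,60
dbp,continuous,81.4,12.0,81.1,14.5,30
chest_pain,binary,0.734,NA,0.535,NA,NA
antiplatelet,binary,0.839,NA,0.493,NA,NA
statin,binary,0.800,NA,0.440,NA,NA
ace_inhibitor,binary,0.242,NA,0.141,NA,NA
calcium_blocker,binary,0.117,NA,0.084,NA,NA
nitrates,binary,0.368,NA,0.198,NA,NA
betablocker,binary,0.501,NA,0.277,NA,NA
hyperlipidemia,binary,0.748,NA,0.537,NA,NA
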