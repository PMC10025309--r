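label,row_type,mean_5,sd_5,mean_10,sd_10,mean_15,sd_15,mean_20,sd_20,mean_25,sd_25,r_squared,p_value
15:0,fa,,,0.17,0.29,,,,,,,0.07,0.23
16:0,fa,11.82,0.78,9.02,1.96,7.06,1.29,8.17,0.72,6.69,1.12,0.56,1.32E-03
18:0,fa,10.58,1.06,4.08,0.81,1.85,0.39,5.76,0.59,6.20,0.68,0.12,0.21
total_normal_saturated,group_total,22.40,1.58,13.27,2.55,8.91,1.67,13.93,1.14,12.89,1.68,0.31,0.031
iso 14:0,fa,,,0.57,0.52,0.33,0.29,,,0.66,0.11,0.07,0.33
iso 15:0,fa,5.13,0.24,4.28,3.71,5.29,0.93,7.06,3.48,8.96,3.64,0.26,0.053
anteiso 15:0,fa,2.20,0.23,3.85,3.45,0.82,0.73,,,0.45,0.02,0.23,0.070
iso 16:0,fa,,,,,,,,,,,,
total_branched_saturated,group_total,7.33,0.29,8.70,0.76,6.44,1.02,7.06,3.48,10.06,3.56,0.06,0.40
15:1,fa,,,,,,,,,,,0.03,0.41
16:1,fa,26.58,1.29,30.16,4.05,26.96,2.18,33.36,5.15,29.27,4.60,0.10,0.261
17:1,fa,3.26,1.52,5.64,0.66,2.77,2.42,0.95,1.63,2.04,1.12,0.24,0.062
18:1,fa,,,,,,,1.02,1.77,,,0.07,0.21
total_normal_unsaturated,group_total,29.84,0.29,35.80,3.97,29.73,0.68,35.33,7.20,31.31,3.52,0.007,0.77
iso 15:1,fa,,,,,,,,,,,,
iso 16:1,fa,,,0.21,0.37,,,,,,,0.07,0.25
total_branched_unsaturated,group_total,,,0.21,0.37,,,,,,,,
total_non_hydroxy,group_total,59.58,1.46,57.99,5.08,45.08,0.48,56.32,7.35,54.27,8.56,0.06,0.36
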