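label,row_type,mean_5,sd_5,mean_6,sd_6,mean_7,sd_7,mean_8,sd_8,r_squared,p_value
15:0,fa,,,0.35,0.30,0.37,0.32,0.48,0.42,0.41,1.94E-05
16:0,fa,6.69,1.12,8.03,1.97,18.15,5.54,9.39,2.66,0.15,0.21
18:0,fa,6.20,0.68,1.28,0.07,2.74,1.13,1.47,1.29,0.45,0.016
total_normal_saturated,group_total,12.89,1.68,9.31,1.94,21.26,5.38,11.34,3.69,0.02,0.64
iso 14:0,fa,0.66,0.11,0.35,0.30,,,,,,
iso 15:0,fa,8.96,3.64,8.00,2.11,8.99,0.54,11.69,1.07,0.21,0.14
anteiso 15:0,fa,0.45,0.02,,,0.53,0.04,0.63,0.04,0.85,2.18E-05
iso 16:0,fa,,,,,,,,,,
total_branched_saturated,group_total,10.06,3.56,8.35,2.23,9.34,0.85,12.33,1.12,0.14,0.23
15:1,fa,,,,,,,0.22,0.38,,
16:1,fa,29.27,4.60,32.75,3.00,32.22,1.98,38.65,4.60,0.46,0.016
17:1,fa,2.04,1.12,2.39,0.13,2.95,0.32,4.19,0.47,0.66,1.32E-03
18:1,fa,,,,,0.33,0.05,0.64,0.16,,
total_normal_unsaturated,group_total,31.31,3.52,35.14,2.90,35.40,2.41,43.49,5.12,0.59,3.33E-03
iso 15:1,fa,,,,,,,,,,
iso 16:1,fa,,,,,,,,,,
total_branched_unsaturated,group_total,,,,,,,,,,
total_non_hydroxy,group_total,54.27,8.56,52.80,5.43,66.01,3.85,67.16,3.07,0.52,7.74E-03
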