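label,row_type,mean_5,sd_5,mean_10,sd_10,mean_15,sd_15,mean_20,sd_20,mean_25,sd_25,r_squared,p_value
15:0,fa,,,,,,,,,,,,
16:0,fa,11.80,0.99,13.18,3.99,12.13,0.98,11.31,1.59,12.09,1.44,0.010,0.73
18:0,fa,4.94,1.54,5.90,3.17,3.42,0.41,6.19,3.21,2.39,0.62,0.23,0.28
total_normal_saturated,group_total,16.74,2.53,19.07,5.50,15.56,1.39,17.50,4.80,14.48,2.06,0.83,0.35
iso 14:0,fa,,,2.80,2.52,,,,,0.13,0.22,,
iso 15:0,fa,5.61,0.37,7.09,1.08,6.03,0.32,7.27,0.61,10.10,1.00,0.59,7.83E-04
anteiso 15:0,fa,2.52,0.22,1.72,1.54,1.49,0.16,0.25,0.44,0.23,0.40,0.81,4.84E-06
iso 16:0,fa,,,,,,,,,,,,
total_branched_saturated,group_total,8.13,0.59,11.60,1.37,7.52,0.20,7.53,0.73,10.45,1.62,0.002,0.88
15:1,fa,,,,,,,,,,,,
16:1,fa,33.69,1.43,33.71,1.87,32.65,2.33,33.11,2.59,30.86,1.29,0.21,0.083
17:1,fa,7.89,1.70,4.49,1.41,2.33,0.28,,,0.57,0.52,0.77,1.85E-05
18:1,fa,0.36,0.34,,,,,,,0.32,0.29,0.09,0.29
total_normal_unsaturated,group_total,41.94,0.38,38.20,0.78,34.99,2.04,33.11,2.59,31.76,2.05,0.83,2.31E-06
iso 15:1,fa,,,,,,,,,,,,
iso 16:1,fa,,,,,,,,,,,,
total_branched_unsaturated,group_total,,,,,,,,,,,,
total_non_hydroxy,group_total,66.82,2.89,68.89,6.23,58.06,3.62,58.13,6.64,56.69,5.08,0.45,6.54E-03
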