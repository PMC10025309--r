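label,row_type,mean_5,sd_5,mean_10,sd_10,mean_15,sd_15,mean_20,sd_20,mean_25,sd_25,r_squared,p_value
15:0,fa,3.08,0.16,4.60,0.18,5.59,0.42,7.45,0.57,9.15,1.10,0.94,2.11E-09
16:0,fa,8.75,5.91,6.25,1.29,6.13,0.92,8.43,0.74,12.81,2.84,0.17,0.12
18:0,fa,2.39,0.83,3.71,0.46,1.57,0.76,1.27,0.49,2.84,0.42,0.05,0.45
total_normal_saturated,group_total,14.21,5.83,14.57,1.78,13.30,1.50,17.17,0.77,24.80,4.11,0.45,6.29E-03
iso 14:0,fa,0.63,0.33,0.47,0.03,0.19,0.32,,,0.68,0.02,0.05,0.42
iso 15:0,fa,18.34,0.37,19.27,0.81,22.86,3.19,24.18,0.55,22.77,1.65,0.54,1.75E-03
anteiso 15:0,fa,5.89,0.07,4.59,0.25,4.01,0.43,2.67,0.14,2.20,0.20,0.96,3.88E-10
iso 16:0,fa,1.07,0.31,1.48,0.19,1.19,0.21,0.86,0.75,0.98,0.03,0.06,0.37
total_branched_saturated,group_total,25.94,0.73,25.82,1.22,28.24,3.11,27.71,1.08,26.63,1.85,0.07,0.34
15:1,fa,1.41,0.19,1.93,0.18,1.92,0.11,1.90,0.09,1.86,0.25,0.25,0.057
16:1,fa,15.61,0.35,15.58,0.70,17.85,1.34,17.88,1.13,18.08,0.63,0.58,1.05E-03
17:1,fa,7.47,2.93,10.86,0.91,8.93,0.81,4.95,2.85,3.87,1.81,0.37,0.017
18:1,fa,,,,,,,,,,,,
total_normal_unsaturated,group_total,24.49,3.29,28.37,0.75,28.45,2.23,24.74,2.45,23.81,1.10,0.07,0.34
iso 15:1,fa,9.73,0.43,8.16,0.44,6.96,0.67,4.54,0.19,4.04,0.14,0.95,8.90E-10
iso 16:1,fa,0.22,0.38,0.48,0.42,0.24,0.41,,,,,0.56,1.27E-03
total_branched_unsaturated,group_total,9.95,0.54,8.64,0.36,7.20,0.33,4.54,0.19,4.04,0.14,0.95,4.29E-10
total_non_hydroxy,group_total,74.60,2.86,77.40,2.90,77.18,5.06,74.15,3.22,79.28,5.00,0.05,0.41
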