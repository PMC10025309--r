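label,row_type,mean_5,sd_5,mean_6,sd_6,mean_7,sd_7,mean_8,sd_8,r_squared,p_value
15:0,fa,8.41,3.27,12.39,0.53,10.34,2.34,9.15,1.10,8.14E-05,0.98
16:0,fa,7.93,2.36,7.50,0.41,7.76,0.70,12.81,2.84,0.38,0.032
18:0,fa,0.86,0.16,0.75,0.28,0.62,0.07,2.84,0.42,0.48,0.013
total_normal_saturated,group_total,17.21,5.44,20.62,0.33,18.73,2.95,24.80,4.11,0.31,0.06
iso 14:0,fa,0.77,0.26,0.42,0.03,0.47,0.05,0.68,0.02,0.02,0.65
iso 15:0,fa,26.47,0.93,25.37,1.24,30.48,1.16,22.77,1.65,0.05,0.48
anteiso 15:0,fa,1.07,0.11,2.06,1.72,1.54,0.15,2.20,0.20,0.15,0.22
iso 16:0,fa,0.09,0.16,,,,,0.98,0.03,,
total_branched_saturated,group_total,28.40,1.19,27.85,1.10,32.50,1.27,26.63,1.85,8.33E-04,0.93
15:1,fa,3.77,0.70,2.70,2.09,2.31,0.41,1.86,0.25,0.35,0.045
16:1,fa,16.02,2.56,15.49,0.80,18.85,0.87,18.08,0.63,0.34,0.047
17:1,fa,4.00,2.20,4.27,0.87,3.15,0.64,3.87,1.81,0.017,0.69
18:1,fa,,,,,,,,,,
total_normal_unsaturated,group_total,23.80,1.59,22.46,2.10,24.32,1.89,23.81,1.10,0.019,0.67
iso 15:1,fa,3.41,0.38,3.23,0.14,3.39,0.23,4.04,0.14,0.38,0.032
iso 16:1,fa,,,,,,,,,0.09,0.14
total_branched_unsaturated,group_total,3.41,0.38,3.23,0.14,3.39,0.23,4.04,0.14,0.38,0.03
total_non_hydroxy,group_total,72.81,5.95,74.16,1.55,78.93,5.83,79.28,5.00,0.30,0.065
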