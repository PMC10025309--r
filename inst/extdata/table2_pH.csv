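label,row_type,mean_5,sd_5,mean_6,sd_6,mean_7,sd_7,mean_8,sd_8,r_squared,p_value
15:0,fa,,,,,,,,,,
16:0,fa,12.09,1.44,13.94,4.77,12.69,1.02,17.08,1.84,0.27,0.081
18:0,fa,2.39,0.62,1.87,0.87,2.40,0.64,3.62,0.67,0.30,0.067
total_normal_saturated,group_total,14.48,2.06,15.82,3.91,15.08,1.35,20.70,2.28,0.38,0.032
iso 14:0,fa,0.13,0.22,0.31,0.53,0.22,0.38,,,0.26,0.092
iso 15:0,fa,10.10,1.00,6.35,0.99,6.50,1.22,9.23,2.24,0.02,0.68
anteiso 15:0,fa,0.23,0.40,,,0.14,0.24,,,,1.30E-02
iso 16:0,fa,,,,,,,,,,
total_branched_saturated,group_total,10.45,1.62,6.65,0.48,6.85,0.91,9.23,2.24,0.04,0.55
15:1,fa,,,,,,,,,,
16:1,fa,30.86,1.29,33.05,1.30,31.54,2.03,7.70,0.78,0.57,4.68E-03
17:1,fa,0.57,0.52,0.46,0.09,0.71,0.05,,,0.05,0.49
18:1,fa,0.32,0.29,3.18,5.50,,,,,,
total_normal_unsaturated,group_total,31.76,2.05,36.69,6.62,32.25,1.99,7.70,0.78,0.53,7.10E-03
iso 15:1,fa,,,,,,,,,,
iso 16:1,fa,,,,,,,,,,
total_branched_unsaturated,group_total,,,,,,,,,,
total_non_hydroxy,group_total,56.69,5.08,59.16,10.09,54.18,3.91,37.62,0.10,0.51,9.20E-03
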