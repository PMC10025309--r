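label,row_type,mean_5,sd_5,mean_6,sd_6,mean_7,sd_7,mean_8,sd_8,r_squared,p_value
iso C_13,fa,1.15,0.36,0.79,0.08,0.54,0.21,0.48,0.03,0.64,1.73E-03
iso C_14,fa,,,0.09,0.08,0.21,0.07,0.31,0.001,0.88,7.93E-06
normal C_14,fa,7.81,2.25,4.66,0.52,5.03,1.05,6.35,0.88,0.07,0.39
iso C_15,fa,65.92,7.93,64.32,4.78,59.69,9.43,49.02,6.17,0.48,0.012
anteiso C_15,fa,0.61,0.11,0.71,0.09,1.28,0.34,1.98,0.19,0.84,2.74E-05
normal C_15,fa,2.35,0.32,2.41,0.03,1.61,0.28,1.60,0.08,0.64,1.79E-03
iso C_16,fa,0.58,0.35,0.71,0.10,1.07,0.32,2.47,0.68,0.67,1.09E-03
normal C_16,fa,10.20,1.90,8.94,1.58,12.29,5.48,14.45,2.69,0.28,0.078
iso C_17,fa,10.84,7.68,16.33,3.67,17.17,5.92,21.89,3.66,0.41,0.026
anteiso C_17,fa,0.13,0.12,0.32,0.05,0.56,0.13,0.75,0.23,0.79,1.07E-04
normal C_17,fa,0.42,0.37,0.72,0.13,0.54,0.07,0.70,0.05,0.14,0.23
normal C_18,fa,,,,,,,,,,
total_iso,class_total,78.49,1.03,82.24,1.18,78.69,3.85,74.17,1.88,0.29,0.070
total_anteiso,class_total,0.73,0.02,1.04,0.05,1.84,0.35,2.72,0.05,0.93,5.20E-07
total_normal,class_total,20.78,1.04,16.72,1.22,19.47,4.20,23.10,1.86,0.12,0.25
iso_over_anteiso,ratio,107.0,2.81,79.48,3.30,43.57,7.11,27.27,1.06,0.97,6.22E-09
iso_over_normal,ratio,3.79,0.23,4.94,0.45,4.19,1.06,3.23,0.36,0.11,0.28
anteiso_over_normal,ratio,0.04,0.02,0.06,0.008,0.10,0.04,0.12,0.009,0.79,1.05E-04
RIAN,index,-0.58,0.03,-0.70,0.04,-0.62,0.12,-0.52,0.05,0.11,0.29
RAN15,index,0.26,0.07,0.30,0.04,0.79,0.08,1.24,0.14,0.88,5.57E-06
RAN17,index,0.31,0.03,0.46,0.02,1.02,0.10,1.07,0.34,0.73,4.20E-04
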