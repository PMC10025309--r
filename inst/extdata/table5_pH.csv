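label,row_type,mean_5,sd_5,mean_6,sd_6,mean_7,sd_7,mean_8,sd_8,r_squared,p_value
iso C_13,fa,,,,,,,,,,
iso C_14,fa,,,,,,,,,,
normal C_14,fa,4.08,1.18,16.07,17.17,4.53,0.51,5.37,0.46,0.010,0.76
iso C_15,fa,35.18,5.23,29.61,0.85,24.80,3.99,31.27,4.10,0.08,0.35
anteiso C_15,fa,2.55,0.64,3.56,0.85,3.15,0.80,3.43,0.25,0.14,0.24
normal C_15,fa,,,,,,,,,,
iso C_16,fa,0.03,0.05,,,,,,,,
normal C_16,fa,9.77,0.30,13.11,1.98,13.71,0.91,12.34,0.95,0.27,0.08
iso C_17,fa,45.15,6.57,32.63,4.49,47.44,4.38,42.78,2.62,0.016,0.70
anteiso C_17,fa,2.43,0.44,4.02,0.46,4.99,0.49,3.79,0.50,0.32,0.053
normal C_17,fa,0.07,0.06,,,,,,,0.36,0.039
normal C_18,fa,0.74,0.15,1.01,0.29,1.37,0.13,1.02,0.12,0.25,0.097
total_iso,class_total,80.36,1.31,62.23,13.74,72.25,1.61,74.05,1.70,0.01,0.72
total_anteiso,class_total,4.97,0.52,7.58,1.24,8.14,0.76,7.22,0.27,0.36,0.04
total_normal,class_total,14.66,0.95,30.18,14.97,19.61,1.07,18.73,1.43,4.7E-04,0.95
iso_over_anteiso,ratio,16.29,1.97,8.15,0.55,8.94,0.06,10.28,0.62,0.33,0.05
iso_over_normal,ratio,5.50,0.44,2.50,1.32,3.69,0.27,3.97,0.39,0.10,0.33
anteiso_over_normal,ratio,0.34,0.03,0.30,0.15,0.42,0.03,0.39,0.01,0.14,0.24
RIAN,index,-0.77,0.03,-0.39,0.30,-0.61,0.03,-0.64,0.04,0.009,0.77
RAN15,index,,,,,,,,,,
RAN17,index,24.38,2.65,,,,,,,,
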