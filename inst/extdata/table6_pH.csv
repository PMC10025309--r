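label,row_type,mean_5,sd_5,mean_6,sd_6,mean_7,sd_7,mean_8,sd_8,r_squared,p_value
iso C_13,fa,,,,,,,,,,
iso C_14,fa,0.03,0.06,0.12,0.06,0.23,0.06,0.27,0.04,0.79,1.24E-04
normal C_14,fa,2.48,1.40,3.55,1.29,3.11,0.64,3.17,0.62,0.04,0.54
iso C_15,fa,37.08,9.96,36.44,5.78,22.08,2.60,26.93,4.94,0.37,0.036
anteiso C_15,fa,6.45,3.19,6.33,1.00,4.55,0.49,6.16,1.26,0.03,0.58
normal C_15,fa,,,0.14,0.25,0.13,0.02,0.17,0.07,0.19,0.15
iso C_16,fa,0.91,0.05,1.02,0.40,2.29,0.18,1.79,0.34,0.51,8.88E-03
normal C_16,fa,5.58,1.78,5.03,1.13,8.26,0.52,7.54,1.41,0.36,0.040
iso C_17,fa,34.01,7.05,37.15,7.24,48.26,1.93,43.61,3.99,0.39,0.029
anteiso C_17,fa,10.81,5.00,9.65,1.40,10.21,1.93,9.25,1.13,0.04,0.55
normal C_17,fa,2.41,1.25,0.30,0.27,0.48,0.26,0.71,0.07,0.31,0.062
normal C_18,fa,0.24,0.10,0.27,0.03,0.40,0.05,0.41,0.09,0.53,7.21E-03
total_iso,class_total,72.03,3.52,74.73,1.25,72.85,2.42,72.60,0.89,7.99E-05,0.98
total_anteiso,class_total,17.26,7.54,15.97,0.50,14.76,2.25,15.41,0.18,0.05,0.48
total_normal,class_total,10.71,4.18,9.30,1.75,12.38,0.18,11.99,0.93,0.12,0.27
iso_over_anteiso,ratio,5.09,3.17,4.68,0.07,5.03,0.91,4.71,0.08,4.23E-03,0.84
iso_over_normal,ratio,7.26,2.08,8.26,1.76,5.89,0.28,6.08,0.55,0.20,0.15
anteiso_over_normal,ratio,1.92,1.18,1.77,0.40,1.19,0.16,1.29,0.11,0.21,0.14
RIAN,index,-0.94,0.18,-0.99,0.09,-0.85,0.007,-0.87,0.04,0.16,0.19
RAN15,index,,,17.39,,34.49,7.10,40.13,11.40,0.45,0.017
RAN17,index,6.27,5.46,22.98,2.18,23.58,7.50,13.10,0.33,0.11,0.29
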