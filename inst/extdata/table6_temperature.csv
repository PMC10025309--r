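label,row_type,mean_5,sd_5,mean_10,sd_10,mean_15,sd_15,mean_20,sd_20,mean_25,sd_25,r_squared,p_value
iso C_13,fa,,,,,,,,,,,,
iso C_14,fa,0.31,0.04,0.34,0.14,0.16,0.01,0.10,0.09,0.03,0.06,0.69,1.39E-04
normal C_14,fa,0.79,0.17,1.25,0.54,1.32,0.33,2.01,0.26,2.48,1.40,0.50,3.37E-03
iso C_15,fa,9.98,1.84,16.57,4.20,13.60,0.82,24.36,5.12,37.08,9.96,0.68,1.41E-04
anteiso C_15,fa,23.04,5.28,26.57,5.97,17.95,1.64,14.45,3.63,6.45,3.19,0.67,1.73E-04
normal C_15,fa,,,,,,,,,,,,
iso C_16,fa,1.78,0.23,1.54,0.32,1.28,0.13,1.40,0.39,0.91,0.05,0.55,1.47E-03
normal C_16,fa,1.91,0.48,1.54,0.49,2.09,0.30,3.77,1.64,5.58,1.78,0.58,9.16E-04
iso C_17,fa,12.65,2.68,13.85,2.78,19.64,0.83,28.86,2.92,34.01,7.05,0.83,2.03E-06
anteiso C_17,fa,48.96,3.95,38.19,8.68,43.64,1.73,24.11,4.32,10.81,5.00,0.77,1.61E-05
normal C_17,fa,0.50,0.26,0.14,0.02,0.19,0.08,0.76,1.07,2.41,1.25,0.37,0.016
normal C_18,fa,0.07,0.06,,,0.12,0.03,0.18,0.03,0.24,0.10,0.59,8.08E-04
total_iso,class_total,24.71,1.84,32.30,2.07,34.69,0.80,54.72,3.29,72.03,3.52,0.90,5.75E-08
total_anteiso,class_total,72.00,2.27,64.76,3.05,61.59,1.00,38.56,0.71,17.26,7.54,0.88,1.97E-07
total_normal,class_total,3.28,0.57,2.94,0.98,3.72,0.22,6.72,2.75,10.71,4.18,0.57,1.12E-03
iso_over_anteiso,ratio,0.34,0.04,0.50,0.06,0.56,0.02,1.42,0.11,5.09,3.17,0.48,4.41E-03
iso_over_normal,ratio,7.63,0.97,11.61,2.82,9.33,0.37,9.07,3.40,7.26,2.08,0.04,0.49
anteiso_over_normal,ratio,22.46,4.64,23.80,7.98,16.59,1.20,6.29,2.04,1.92,1.18,0.78,1.33E-05
RIAN,index,-1.47,0.08,-1.53,0.14,-1.41,0.03,-1.16,0.18,-0.94,0.18,0.67,1.74E-04
RAN15,index,,,,,,,,,,,,
RAN17,index,126.5,86.2,275.4,91.9,258.3,127.3,46.6,45.6,6.27,5.46,0.25,0.057
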