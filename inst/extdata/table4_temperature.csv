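label,row_type,mean_5,sd_5,mean_10,sd_10,mean_15,sd_15,mean_20,sd_20,mean_25,sd_25,r_squared,p_value
iso C_13,fa,0.15,0.006,0.28,0.02,0.33,0.06,0.42,0.03,0.48,0.03,0.91,2.59E-08
iso C_14,fa,0.52,0.03,0.45,0.04,0.44,0.15,0.37,0.04,0.31,0.001,0.55,1.45E-03
normal C_14,fa,2.88,0.15,3.06,0.45,3.22,0.31,3.69,0.08,6.35,0.88,0.64,3.51E-04
iso C_15,fa,46.17,1.43,53.41,5.32,56.37,10.02,54.64,4.40,49.02,6.17,0.02,0.58
anteiso C_15,fa,3.74,0.16,3.08,0.26,2.45,0.29,1.88,0.22,1.98,0.19,0.85,1.10E-06
normal C_15,fa,0.72,0.008,0.79,0.08,0.81,0.28,1.10,0.05,1.60,0.08,0.73,4.78E-05
iso C_16,fa,6.92,0.62,4.27,0.89,3.77,0.28,3.14,0.54,2.47,0.68,0.68,1.42E-04
normal C_16,fa,7.10,0.21,5.88,0.76,5.53,2.43,7.44,1.64,14.45,2.69,0.41,9.94E-03
iso C_17,fa,26.93,0.79,26.30,3.79,25.40,3.92,25.95,2.23,21.89,3.66,0.23,0.073
anteiso C_17,fa,4.81,0.30,2.44,0.53,1.62,0.86,1.05,0.19,0.75,0.23,0.79,8.29E-06
normal C_17,fa,0.07,0.06,0.04,0.07,0.07,0.12,0.32,0.04,0.70,0.05,0.71,7.94E-05
normal C_18,fa,,,,,,,,,,,,
total_iso,class_total,80.69,0.16,84.71,0.74,86.31,4.27,84.52,1.75,74.17,1.88,0.16,0.15
total_anteiso,class_total,8.55,0.13,5.52,0.29,4.07,1.15,2.93,0.35,2.72,0.05,0.85,1.15E-06
total_normal,class_total,10.77,0.13,9.77,0.45,9.62,3.13,12.56,1.61,23.10,1.86,0.54,1.81E-03
iso_over_anteiso,ratio,9.44,0.15,15.39,0.97,22.42,6.39,29.16,3.75,27.27,1.06,0.79,1.05E-05
iso_over_normal,ratio,7.50,0.10,8.68,0.49,9.65,3.17,6.82,1.06,3.23,0.36,0.34,0.023
anteiso_over_normal,ratio,0.79,0.02,0.56,0.005,0.43,0.03,0.24,0.04,0.12,0.009,0.98,6.79E-13
RIAN,index,-0.92,0.006,-0.97,0.02,-0.99,0.15,-0.85,0.07,-0.52,0.05,0.51,2.87E-03
RAN15,index,5.22,0.27,3.96,0.75,3.17,0.67,1.70,0.16,1.24,0.14,0.92,2.31E-08
RAN17,index,44.80,2.33,24.44,,12.51,,3.30,0.21,1.07,0.34,0.92,1.26E-08
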