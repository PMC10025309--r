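label,row_type,mean_5,sd_5,mean_10,sd_10,mean_15,sd_15,mean_20,sd_20,mean_25,sd_25,r_squared,p_value
iso C_13,fa,,,,,,,,,,,,
iso C_14,fa,0.19,0.06,,,,,,,,,,
normal C_14,fa,3.70,0.62,3.89,0.47,4.57,1.04,4.66,1.12,4.08,1.18,0.07,0.36
iso C_15,fa,13.93,3.19,22.37,0.47,21.24,3.39,28.68,6.91,35.18,5.23,0.72,6.29E-05
anteiso C_15,fa,14.61,3.09,15.57,1.77,10.24,2.26,6.31,1.73,2.55,0.64,0.82,3.12E-06
normal C_15,fa,,,,,,,,,,,,
iso C_16,fa,2.38,0.27,1.40,0.30,0.88,0.11,0.37,0.14,0.03,0.05,0.93,9.88E-09
normal C_16,fa,20.44,1.59,14.45,1.26,18.51,1.48,13.87,2.03,9.77,0.30,0.62,4.59E-04
iso C_17,fa,18.76,1.50,21.28,2.06,29.04,2.73,36.42,6.20,45.15,6.57,0.86,7.20E-07
anteiso C_17,fa,25.53,3.49,20.25,1.95,14.96,2.35,8.71,1.39,2.43,0.44,0.95,5.19E-10
normal C_17,fa,0.18,0.08,0.54,0.94,0.16,0.06,0.36,0.14,0.07,0.06,0.02,0.61
normal C_18,fa,0.29,0.02,0.25,0.21,0.40,0.005,0.63,0.09,0.74,0.15,0.70,1.08E-03
total_iso,class_total,35.26,1.50,45.05,1.65,51.16,0.60,65.47,0.71,80.36,1.31,0.97,2.19E-11
total_anteiso,class_total,40.13,0.41,35.82,1.04,25.20,0.09,15.02,0.40,4.97,0.52,0.98,7.88E-13
total_normal,class_total,24.60,1.11,19.13,1.35,23.64,0.52,19.51,0.95,14.66,0.95,0.57,1.12E-03
iso_over_anteiso,ratio,0.88,0.05,1.26,0.07,2.03,0.03,4.36,0.11,16.29,1.97,0.68,1.69E-04
iso_over_normal,ratio,1.44,0.13,2.37,0.25,2.17,0.07,3.36,0.20,5.50,0.44,0.82,3.23E-06
anteiso_over_normal,ratio,1.63,0.06,1.88,0.15,1.07,0.02,0.77,0.06,0.34,0.03,0.86,7.36E-07
RIAN,index,-0.49,0.03,-0.63,0.04,-0.51,0.01,-0.62,0.03,-0.77,0.03,0.57,1.08E-03
RAN15,index,,,,,,,,,,,,
RAN17,index,162.0,69.0,13.8,8.0,103.7,37.4,27.89,13.98,24.38,2.65,0.51,2.92E-03
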