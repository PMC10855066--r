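protein,compound,temperature_k,ksv_e4,ksv_se_e4,kq_e12,log_kb,log_kb_se,kb_e4,n,n_se,dg_kjmol,dh_kjmol,ds_jmolk
aag,1,297,6.60,0.10,11.0,4.49,0.07,3.09,0.94,0.01,-27.11,-155.65,-432.83
aag,1,303,4.94,0.18,8.23,4.10,0.30,1.26,0.90,0.05,NA,NA,NA
aag,1,308,3.55,0.27,5.92,3.49,0.29,0.31,0.82,0.08,NA,NA,NA
aag,2,297,26.15,0.53,43.58,4.66,0.10,4.57,0.87,0.02,-26.17,-109.55,-280.76
aag,2,303,13.58,0.59,22.63,4.17,0.15,1.48,0.83,0.03,NA,NA,NA
aag,2,308,13.45,0.68,22.42,3.98,0.20,0.95,0.84,0.02,NA,NA,NA
aag,3,297,26.12,0.56,43.53,4.66,0.10,4.57,0.87,0.02,-25.40,-159.25,-450.70
aag,3,303,13.68,0.57,22.80,3.91,0.26,0.81,0.79,0.04,NA,NA,NA
aag,3,308,12.30,0.86,20.50,3.47,0.30,0.29,0.71,0.08,NA,NA,NA
aag,4,297,43.26,1.24,72.10,4.70,0.07,5.01,0.83,0.02,-26.78,-80.00,-165.70
aag,4,303,23.88,1.40,39.80,4.47,0.23,2.95,0.84,0.04,NA,NA,NA
aag,4,308,20.21,1.37,33.68,4.22,0.18,1.66,0.81,0.03,NA,NA,NA
aag,5,297,55.71,2.78,92.85,4.15,0.07,1.41,0.72,0.02,-23.77,-93.87,-236.03
aag,5,303,23.91,1.43,39.85,3.95,0.13,0.89,0.76,0.02,NA,NA,NA
aag,5,308,22.56,1.82,37.6,3.54,0.12,0.35,0.69,0.02,NA,NA,NA
gg,1,297,10.24,0.36,17.07,5.19,0.17,15.48,1.03,0.03,-29.44,-155.02,-422.85
gg,1,303,9.29,0.33,15.48,4.60,0.14,3.98,0.94,0.04,NA,NA,NA
gg,1,308,7.14,0.22,11.90,4.22,0.15,1.66,0.89,0.03,NA,NA,NA
gg,2,297,18.81,0.49,31.35,5.19,0.20,15.49,0.99,0.04,-29.67,-97.62,-228.80
gg,2,303,11.15,0.39,18.58,4.94,0.24,8.71,0.98,0.03,NA,NA,NA
gg,2,308,7.21,0.20,12.02,4.57,0.23,3.72,0.95,0.04,NA,NA,NA
gg,3,297,9.65,0.11,16.08,4.57,0.09,3.72,0.93,0.02,-26.13,-78.71,-177.09
gg,3,303,9.20,0.41,15.33,4.37,0.10,2.34,0.90,0.03,NA,NA,NA
gg,3,308,7.11,0.34,11.85,4.07,0.13,1.17,0.86,0.04,NA,NA,NA
gg,4,297,20.01,0.48,33.35,5.34,0.13,21.88,1.01,0.02,-30.32,-71.87,-139.92
gg,4,303,16.00,0.46,26.67,5.07,0.21,11.75,0.98,0.04,NA,NA,NA
gg,4,308,14.67,0.55,24.45,4.89,0.17,7.76,0.95,0.03,NA,NA,NA
gg,5,297,18.68,0.33,31.13,6.01,0.08,102.33,1.12,0.02,-34.12,-54.02,-67.01
gg,5,303,16.05,0.44,26.75,5.83,0.20,67.61,1.11,0.04,NA,NA,NA
gg,5,308,12.94,0.74,21.57,5.66,0.23,45.71,1.10,0.04,NA,NA,NA
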