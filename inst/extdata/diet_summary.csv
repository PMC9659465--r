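panel,item,exp1_mean,exp1_rsd,ref,d1,d2,d3,d4,d5,sem,p_value,exp3_mean,exp3_rsd
wheat,abw,462.16,5.18,414.34,440.66,450.63,429.38,425.96,407.04,4.46,0.20,445.21,2.53
wheat,fi,64.16,7.37,56.37,51.43,71.08,68.27,65.59,56.29,2.16,0.02,59.38,6.25
wheat,adg,62.52,15.85,38.64,42.50,43.58,37.86,45.08,31.86,1.66,0.24,32.08,12.16
wheat,fcr,1.04,11.67,1.53,1.48,1.65,1.82,1.46,1.83,0.07,0.51,1.86,7.97
wheat,amei,1.62,5.45,1.38,1.34,1.66,1.58,1.57,1.27,0.03,<0.01,1.35,6.04
wheat,nei,1.13,8.83,0.85,0.77,1.02,1.02,1.00,0.78,0.03,0.05,0.91,6.44
wheat,thp,0.94,11.23,0.98,1.02,1.09,1.02,1.03,0.94,0.01,0.75,0.89,3.50
wheat,hi,0.49,21.49,0.53,0.57,0.64,0.57,0.58,0.49,0.01,0.18,0.44,6.22
wheat,re,0.68,14.70,0.41,0.32,0.57,0.57,0.55,0.33,0.03,0.05,0.46,15.39
wheat,rq,0.99,3.49,1.00,1.01,0.98,0.98,0.99,0.99,<0.01,0.46,0.94,4.04
wheat,ame,14.72,1.65,13.29,12.55,12.40,12.91,12.63,12.49,0.25,0.93,12.94,1.63
wheat,amen,14.28,1.61,13.06,12.35,12.16,12.63,12.37,12.24,0.24,0.92,12.34,3.07
wheat,ne,10.26,8.17,8.20,7.22,8.05,8.33,8.47,7.60,0.18,0.32,8.65,2.68
wheat,ame_ge,76.67,1.65,72.73,65.91,65.83,59.36,65.54,66.97,1.69,0.65,70.39,1.63
wheat,amen_ge,74.38,1.61,71.45,65.80,65.69,59.25,65.39,66.83,1.66,0.84,67.10,3.05
wheat,ne_ame,69.71,8.35,62.04,56.84,60.81,60.22,62.95,60.76,0.96,0.58,66.79,1.78
wheat,ne_amen,71.86,8.38,63.15,57.73,62.21,61.61,64.44,61.99,1.00,0.54,70.04,1.77
wheat_bran,abw,462.16,5.18,414.34,362.32,368.65,354.59,358.69,321.40,6.65,0.01,347.33,2.45
wheat_bran,fi,64.16,7.37,56.37,57.04,56.43,56.42,55.17,50.42,1.11,0.64,53.28,2.53
wheat_bran,adg,62.52,15.85,38.64,37.29,35.24,37.56,45.00,34.87,1.69,0.62,38.51,7.02
wheat_bran,fcr,1.04,11.67,1.53,1.72,1.65,1.57,1.28,1.57,0.05,0.28,1.39,9.28
wheat_bran,amei,1.62,5.45,1.38,1.23,1.21,1.19,1.24,1.20,0.02,0.05,1.23,4.08
wheat_bran,nei,1.13,8.83,0.86,0.70,0.65,0.60,0.67,0.64,0.02,0.03,0.66,13.68
wheat_bran,thp,0.94,11.23,0.98,0.97,1.00,1.04,1.02,1.01,0.02,0.81,1.02,11.31
wheat_bran,hi,0.49,21.49,0.53,0.53,0.55,0.59,0.57,0.56,0.02,0.81,0.57,20.23
wheat_bran,re,0.68,14.70,0.41,0.25,0.21,0.16,0.22,0.19,0.02,0.03,0.21,42.53
wheat_bran,rq,0.99,3.49,1.00,0.99,0.98,1.01,0.99,0.99,<0.01,0.54,1.01,2.50
wheat_bran,ame,14.72,1.65,13.29,11.22,10.88,11.05,11.33,11.12,0.20,<0.01,11.04,1.74
wheat_bran,amen,14.28,1.61,13.06,11.03,10.67,10.88,11.13,10.95,0.20,<0.01,10.89,1.46
wheat_bran,ne,10.26,8.17,8.20,6.38,5.72,5.82,5.88,6.07,0.16,<0.01,8.19,13.30
wheat_bran,ame_ge,76.67,1.65,72.73,58.89,55.81,57.55,59.79,58.73,1.20,<0.01,63.85,1.74
wheat_bran,amen_ge,74.38,1.61,71.45,58.78,55.70,57.45,59.68,58.63,1.09,<0.01,63.00,1.46
wheat_bran,ne_ame,69.71,8.35,62.04,57.07,54.16,52.16,51.29,53.41,0.61,0.13,74.20,14.95
wheat_bran,ne_amen,71.86,8.38,63.15,58.11,55.26,52.98,52.19,54.25,0.62,0.12,75.22,14.68
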