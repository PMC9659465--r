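diet_id,dm,ge,cp,basis
exp1_ref,88.26,16.94,20.65,air_dry
ref,93.63,18.27,21.04,air_dry
test_wheat_1,92.84,17.68,18.34,air_dry
test_wheat_2,94.25,17.76,19.96,air_dry
test_wheat_3,93.81,17.79,19.53,air_dry
test_wheat_4,92.60,17.85,20.43,air_dry
test_wheat_5,93.99,17.52,20.10,air_dry
test_bran_1,93.44,17.80,20.42,air_dry
test_bran_2,92.74,17.62,20.46,air_dry
test_bran_3,92.40,17.75,20.11,air_dry
test_bran_4,94.27,17.86,20.60,air_dry
test_bran_5,95.25,18.05,20.98,air_dry
test_wheat_v,90.10,18.39,20.06,air_dry
test_bran_v,92.10,17.28,20.59,air_dry
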