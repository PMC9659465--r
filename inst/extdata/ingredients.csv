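ingredient_id,kind,dm,cp,ee,cf,ndf,adf,st,ge,dm_source
wheat_1,wheat,88.60,14.75,1.92,2.71,39.39,4.63,646.73,,assayed
wheat_2,wheat,91.20,14.01,1.75,2.30,35.31,3.62,627.19,,assayed
wheat_3,wheat,89.30,14.78,2.02,2.13,33.93,3.25,665.17,,assayed
wheat_4,wheat,83.20,14.53,2.04,2.28,40.26,3.73,682.69,,assayed
wheat_5,wheat,85.00,14.21,2.24,2.82,39.18,3.53,672.94,,assayed
wheat_v,wheat,87.80,14.45,2.05,3.53,38.15,4.78,602.51,,assayed
bran_1,wheat_bran,88.10,18.04,4.43,14.07,48.01,15.32,149.83,,assayed
bran_2,wheat_bran,87.90,17.23,4.31,14.30,48.58,16.00,145.29,,assayed
bran_3,wheat_bran,87.20,18.17,4.43,14.19,48.69,15.44,150.23,,assayed
bran_4,wheat_bran,88.80,18.30,4.20,13.96,46.77,15.78,143.02,,assayed
bran_5,wheat_bran,88.10,18.02,4.31,14.07,48.47,16.91,140.75,,assayed
bran_v,wheat_bran,87.70,17.868,4.33,14.03,49.03,15.85,161.92,,assayed
corn,other,86.0,,,,,,,,nominal
soybean_meal,other,89.0,,,,,,,,nominal
corn_gluten_meal,other,90.1,,,,,,,,nominal
peanut_meal,other,92.0,,,,,,,,nominal
soybean_oil,other,99.6,,,,,,,,nominal
ddgs,other,90.0,,,,,,,,nominal
lysine_hcl,other,98.5,,,,,,,,nominal
dl_methionine,other,99.0,,,,,,,,nominal
threonine,other,98.5,,,,,,,,nominal
tryptophan,other,98.5,,,,,,,,nominal
monocalcium_phosphate,other,97.0,,,,,,,,nominal
salt,other,99.5,,,,,,,,nominal
sodium_humate,other,90.0,,,,,,,,nominal
choline_chloride,other,98.0,,,,,,,,nominal
sodium_bicarbonate,other,99.0,,,,,,,,nominal
calcium_propionate,other,98.0,,,,,,,,nominal
coarse_stone,other,99.0,,,,,,,,nominal
premix,other,95.0,,,,,,,,nominal
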