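subject,sex,age_years,mass_kg,ul_length_m,al_length_catapult_m,al_length_sprinter_m,al_length_xtend_m
1,male,23,82.59,1.00,1.04,1.05,1.04
2,male,25,87.87,0.88,0.94,0.92,0.96
3,female,29,75.62,0.94,1.01,0.96,1.01
4,male,31,74.38,1.01,1.04,1.03,1.03
5,male,22,71.69,0.90,0.94,0.92,0.93
6,male,33,92.66,0.99,1.05,1.05,1.05
7,male,34,66.69,0.96,1.04,1.00,1.01
8,male,37,90.73,0.95,1.02,1.01,1.00
9,female,29,58.25,0.81,0.86,0.88,0.87
10,female,21,59.51,0.84,0.88,0.88,0.88
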