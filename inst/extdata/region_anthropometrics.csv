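country,weight_men_kg,weight_women_kg,height_men_m,height_women_m,bmi_men,bmi_women
Germany,87.8,71.4,1.80,1.66,27.1,25.9
USA,91.5,78.9,1.77,1.63,29.3,29.7
Japan,70.7,55.3,1.72,1.58,24.0,22.1
Nigeria,67.9,62.2,1.70,1.58,23.6,25.0
Brazil,82.5,72.9,1.75,1.62,26.9,27.8
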