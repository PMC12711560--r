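nutrient,pct_mean,pct_sd,pct_q10,pct_q90
protein_g,50.7,13.6,36.5,66.6
fat_g,5.6,1.5,3.3,8.7
energy_kcal,5.7,1.5,3.9,7.7
vitb12_ug,126.4,33.8,59.6,218.7
iron_mg,39.2,10.5,22.7,61.1
vitb2_mg,36.8,9.8,23.9,52.7
vitb3_mg,33.5,9.0,20.4,50.5
selenium_ug,31.6,8.5,22.9,41.4
zinc_mg,23.3,6.2,11.5,39.2
vitb1_mg,18.1,4.8,10.5,28.4
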