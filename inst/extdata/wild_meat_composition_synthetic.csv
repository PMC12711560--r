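nutrient,value,unit,taxon_id
energy_kcal,112,kcal/100g,taxon_001
energy_kcal,126,kcal/100g,taxon_002
energy_kcal,119,kcal/100g,taxon_003
energy_kcal,133,kcal/100g,taxon_004
protein_g,21.5,g/100g,taxon_001
protein_g,22.8,g/100g,taxon_002
protein_g,20.1,g/100g,taxon_003
protein_g,23.4,g/100g,taxon_004
protein_g,19.6,g/100g,taxon_005
fat_g,2.4,g/100g,taxon_001
fat_g,4.8,g/100g,taxon_002
fat_g,3.1,g/100g,taxon_003
fat_g,5.6,g/100g,taxon_004
iron_mg,2.9,mg/100g,taxon_001
iron_mg,3.4,mg/100g,taxon_002
iron_mg,2.5,mg/100g,taxon_003
zinc_mg,3.2,mg/100g,taxon_001
zinc_mg,2.6,mg/100g,taxon_002
zinc_mg,4.1,mg/100g,taxon_003
selenium_ug,9.5,ug/100g,taxon_001
selenium_ug,11.2,ug/100g,taxon_002
vitb1_mg,0.09,mg/100g,taxon_001
vitb1_mg,0.14,mg/100g,taxon_002
vitb1_mg,0.11,mg/100g,taxon_003
vitb2_mg,0.21,mg/100g,taxon_001
vitb2_mg,0.28,mg/100g,taxon_002
vitb2_mg,0.17,mg/100g,taxon_003
vitb3_mg,5.6,mg/100g,taxon_001
vitb3_mg,6.8,mg/100g,taxon_002
vitb3_mg,4.4,mg/100g,taxon_003
vitb12_ug,1.6,ug/100g,taxon_001
vitb12_ug,2.3,ug/100g,taxon_002
vitb12_ug,1.1,ug/100g,taxon_003
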