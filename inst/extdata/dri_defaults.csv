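group,nutrient,value,unit,rule
children,energy_kcal,1500,kcal/day,EER
women,energy_kcal,2000,kcal/day,EER
men,energy_kcal,2600,kcal/day,EER
children,protein_g,15,g/day,EAR
women,protein_g,38,g/day,EAR
men,protein_g,46,g/day,EAR
children,fat_g,45.8,g/day,AMDR-midpoint
women,fat_g,61.1,g/day,AMDR-midpoint
men,fat_g,79.4,g/day,AMDR-midpoint
children,iron_mg,4.1,mg/day,EAR
women,iron_mg,8.1,mg/day,EAR
men,iron_mg,6,mg/day,EAR
children,zinc_mg,4,mg/day,EAR
women,zinc_mg,6.8,mg/day,EAR
men,zinc_mg,9.4,mg/day,EAR
children,selenium_ug,23,ug/day,EAR
women,selenium_ug,45,ug/day,EAR
men,selenium_ug,45,ug/day,EAR
children,vitb1_mg,0.5,mg/day,EAR
women,vitb1_mg,0.9,mg/day,EAR
men,vitb1_mg,1,mg/day,EAR
children,vitb2_mg,0.5,mg/day,EAR
women,vitb2_mg,0.9,mg/day,EAR
men,vitb2_mg,1.1,mg/day,EAR
children,vitb3_mg,6,mg/day,EAR
women,vitb3_mg,11,mg/day,EAR
men,vitb3_mg,12,mg/day,EAR
children,vitb12_ug,1,ug/day,EAR
women,vitb12_ug,2,ug/day,EAR
men,vitb12_ug,2,ug/day,EAR
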