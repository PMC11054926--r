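nutrient_id,target,unit,basis,direction,strict,energy_relative_rule
saturated_fat,10,pct_kcal,DGA_limit,limit,TRUE,NA
omega3_pufa,1.6,g,AI,minimum,FALSE,NA
linoleic_acid,17,g,AI,minimum,FALSE,NA
fiber,59,g,AI,minimum,FALSE,14
vitamin_a,900,mcg_RAE,RDA,minimum,FALSE,NA
vitamin_b6,1.3,mg,RDA,minimum,FALSE,NA
folate,400,mcg,RDA,minimum,FALSE,NA
vitamin_b12,2.4,mcg,RDA,minimum,FALSE,NA
vitamin_c,90,mg,RDA,minimum,FALSE,NA
vitamin_d,600,IU,RDA,minimum,FALSE,NA
vitamin_e,15,mg,RDA,minimum,FALSE,NA
calcium,1000,mg,RDA,minimum,FALSE,NA
iron,8,mg,RDA,minimum,FALSE,NA
magnesium,400,mg,RDA,minimum,FALSE,NA
phosphorus,700,mg,RDA,minimum,FALSE,NA
potassium,3400,mg,AI,minimum,FALSE,NA
sodium,2300,mg,CDRR,limit,FALSE,NA
zinc,11,mg,RDA,minimum,FALSE,NA
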